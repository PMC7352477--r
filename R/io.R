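#' Read a spliced-junction count matrix
#'
#' Reads a transcripts x samples matrix of non-negative integer
#' spliced-junction counts, auto-detecting the dialect by extension:
#' \code{.tsv}/\code{.txt} (tab-separated, first column transcript ids, header
#' row of sample ids) or \code{.mtx} (MatrixMarket with \code{<path>.rownames}
#' and \code{<path>.colnames} sidecar files, one id per line). Row and column
#' order are preserved from the file.
#'
#' @param path Path to the matrix file.
#' @return Integer matrix with transcript row names and sample column names.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      stop("MTX sidecar name files do not match matrix dimensions")
    }
    dimnames(m) <- list(rn, cn)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    rn <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- rn
  }
  check_count_matrix(m)
  storage.mode(m) <- "integer"
  m
}

check_count_matrix <- function(m) {
  if (anyDuplicated(rownames(m))) {
    stop("duplicated transcript id(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicated sample id(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (!is.numeric(m)) stop("counts must be numeric")
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count at transcript '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  invisible(m)
}

#' Write a count matrix as TSV or MatrixMarket
#'
#' Inverse of [read_counts()]; the dialect follows the file extension.
#' @param counts Integer matrix with dimnames.
#' @param path Output path (\code{.tsv} or \code{.mtx}).
#' @return Invisibly, \code{path}.
#' @export
write_counts <- function(counts, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rownames"))
    writeLines(colnames(counts), paste0(path, ".colnames"))
  } else {
    df <- data.frame(transcript_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a sample annotation table
#'
#' CSV with required columns \code{sample_id}, \code{class} (sarcoma/control),
#' \code{series} (training/evaluation/validation), and optional
#' \code{subtype}, \code{age}, \code{gender}. If \code{counts} is supplied the
#' annotation must cover its sample columns exactly.
#'
#' @param path CSV path.
#' @param counts Optional count matrix to cross-check sample ids against.
#' @return data.frame of sample annotation.
#' @export
read_annotation <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(ann) == 0) stop("no samples in annotation file")
  check_annotation(ann, counts)
}

#' @rdname read_annotation
#' @param ann Annotation data.frame to validate in place of a file.
#' @export
check_annotation <- function(ann, counts = NULL) {
  required <- c("sample_id", "class", "series")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols)) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(ann) == 0) stop("no samples in annotation")
  bad_class <- setdiff(unique(ann$class), c("sarcoma", "control"))
  if (length(bad_class)) stop("unknown class label(s): ", paste(bad_class, collapse = ", "))
  bad_series <- setdiff(unique(ann$series), c("training", "evaluation", "validation"))
  if (length(bad_series)) stop("unknown series label(s): ", paste(bad_series, collapse = ", "))
  if (anyDuplicated(ann$sample_id)) stop("duplicated sample_id in annotation")
  if (!is.null(counts)) {
    orphans <- setdiff(colnames(counts), ann$sample_id)
    if (length(orphans)) {
      stop("sample(s) in count matrix missing from annotation: ",
           paste(orphans, collapse = ", "))
    }
    extra <- setdiff(ann$sample_id, colnames(counts))
    if (length(extra)) {
      stop("annotation sample(s) absent from count matrix: ",
           paste(extra, collapse = ", "))
    }
  }
  ann
}

#' Write sample annotation / ground truth as CSV
#' @param x data.frame.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_annotation <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration with the published swarm search bounds
#'
#' Collects every tunable of the pipeline. The four swarm bounds default to
#' the published search ranges: library-size correlation floor in
#' \code{[-0.1, 1.0]}, FDR threshold in \code{[1e-5, 1.0]}, absolute
#' label-correlation threshold in \code{[0.5, 1.0]}, and ranked-transcript
#' count in \code{[200, n_detected]} (capped at run time by the number of
#' detected transcripts).
#'
#' @param n_particles Swarm size per iteration (published default 100).
#' @param n_iterations Swarm iterations (published default 10).
#' @param inertia,cognitive,social PSO update constants.
#' @param bounds List of length-2 numeric ranges: \code{libsize_cor},
#'   \code{fdr}, \code{cor}, \code{n_ranked}.
#' @param kernel SVM kernel (only \code{"radial"} supported).
#' @param cutoff TEP-score decision cutoff, default 0.5.
#' @param min_total_reads,min_samples_expressed Coverage filter thresholds.
#' @param boot_resamples Bootstrap resamples for AUC confidence intervals.
#' @param seed Master integer seed.
#' @param out_dir Output directory for artifact-writing helpers.
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(n_particles = 100L, n_iterations = 10L,
                       inertia = 0.72, cognitive = 1.49, social = 1.49,
                       bounds = list(libsize_cor = c(-0.1, 1.0),
                                     fdr = c(1e-5, 1.0),
                                     cor = c(0.5, 1.0),
                                     n_ranked = c(200, 3799)),
                       kernel = "radial", cutoff = 0.5,
                       min_total_reads = 30L, min_samples_expressed = 3L,
                       boot_resamples = 2000L,
                       seed = 1L, out_dir = ".") {
  cfg <- list(n_particles = as.integer(n_particles),
              n_iterations = as.integer(n_iterations),
              inertia = inertia, cognitive = cognitive, social = social,
              bounds = bounds, kernel = kernel, cutoff = cutoff,
              min_total_reads = as.integer(min_total_reads),
              min_samples_expressed = as.integer(min_samples_expressed),
              boot_resamples = as.integer(boot_resamples),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  b <- cfg$bounds
  need <- c("libsize_cor", "fdr", "cor", "n_ranked")
  if (!all(need %in% names(b))) stop("bounds must name: ", paste(need, collapse = ", "))
  for (k in need) {
    if (length(b[[k]]) != 2L || b[[k]][1] > b[[k]][2]) stop("invalid bounds for ", k)
  }
  if (b$libsize_cor[1] < -1 || b$libsize_cor[2] > 1) stop("libsize_cor bounds outside [-1, 1]")
  if (b$fdr[1] <= 0 || b$fdr[2] > 1) stop("fdr bounds outside (0, 1]")
  if (b$cor[1] < 0 || b$cor[2] > 1) stop("cor bounds outside [0, 1]")
  if (b$n_ranked[1] < 1) stop("n_ranked lower bound must be >= 1")
  if (cfg$cutoff <= 0 || cfg$cutoff >= 1) stop("cutoff must be in (0, 1)")
  if (cfg$n_particles < 2) stop("need at least 2 particles")
  if (cfg$n_iterations < 1) stop("need at least 1 iteration")
  invisible(cfg)
}

#' Read / write a run configuration as flat YAML
#' @param path YAML path.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  bounds <- list(libsize_cor = unlist(y$bounds$libsize_cor),
                 fdr = unlist(y$bounds$fdr),
                 cor = unlist(y$bounds$cor),
                 n_ranked = unlist(y$bounds$n_ranked))
  args <- y[setdiff(names(y), "bounds")]
  do.call(run_config, c(args, list(bounds = bounds)))
}

#' @rdname read_run_config
#' @param config A [run_config()] object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
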