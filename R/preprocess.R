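#' Remove transcripts with insufficient spliced-read coverage
#'
#' Keeps transcripts whose total count across samples is at least
#' \code{min_total} AND that are expressed (count > 0) in at least
#' \code{min_samples} samples. The sample set is unchanged. Idempotent.
#'
#' @param counts Integer count matrix (transcripts x samples).
#' @param min_total Minimum total spliced reads across all samples.
#' @param min_samples Minimum number of samples with a non-zero count.
#' @return The filtered count matrix.
#' @export
filter_low_coverage <- function(counts, min_total = 30L, min_samples = 3L) {
  stopifnot(min_total >= 0, min_samples >= 0)
  keep <- rowSums(counts) >= min_total & rowSums(counts > 0) >= min_samples
  if (!any(keep)) stop("coverage filter removed every transcript")
  counts[keep, , drop = FALSE]
}

#' Normalize spliced-junction counts to log2 counts-per-million
#'
#' \code{value[t, s] = log2(1e6 * count[t, s] / libsize[s] + 1)} with
#' \code{libsize[s]} the total spliced reads of sample \code{s}. The
#' pseudocount of 1 maps zero counts to exactly 0.
#'
#' @param counts Integer count matrix.
#' @return An object of class \code{"tep_norm"}: list with \code{values}
#'   (log2-CPM matrix) and \code{libsizes} (named per-sample totals).
#' @export
normalize_cpm <- function(counts) {
  libsizes <- colSums(counts)
  if (any(libsizes == 0)) {
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[libsizes == 0], collapse = ", "))
  }
  values <- log2(sweep(counts, 2, libsizes, "/") * 1e6 + 1)
  structure(list(values = values, libsizes = libsizes), class = "tep_norm")
}

#' @export
print.tep_norm <- function(x, ...) {
  cat(sprintf("log2-CPM matrix: %d transcripts x %d samples (median libsize %s)\n",
              nrow(x$values), ncol(x$values),
              format(stats::median(x$libsizes), big.mark = ",")))
  invisible(x)
}

# subset a tep_norm by sample ids and/or transcript ids
subset_norm <- function(norm, samples = NULL, transcripts = NULL) {
  v <- norm$values
  l <- norm$libsizes
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    l <- l[samples]
  }
  if (!is.null(transcripts)) v <- v[transcripts, , drop = FALSE]
  structure(list(values = v, libsizes = l), class = "tep_norm")
}

#' Library-size correlation filter
#'
#' Keeps transcript \code{t} iff the Pearson correlation between its
#' normalized values and log2 library size lies in \code{[lo, hi]}.
#' Transcripts with zero variance are assigned r = 0 so the filter is total.
#' This is the filter whose lower bound the swarm tunes (search range
#' \code{[-0.1, 1.0]}): transcripts tracking sequencing depth rather than
#' biology are strongly anti- or un-correlated candidates for removal.
#'
#' @param norm A [normalize_cpm()] object.
#' @param lo,hi Correlation interval, \code{-1 <= lo <= hi <= 1}.
#' @return Character vector of kept transcript ids (input order).
#' @export
libsize_correlation_filter <- function(norm, lo = -0.1, hi = 1.0) {
  stopifnot(lo >= -1, hi <= 1, lo <= hi)
  if (ncol(norm$values) < 3) stop("need at least 3 samples for correlation filtering")
  r <- libsize_correlation(norm)
  rownames(norm$values)[r >= lo & r <= hi]
}

#' @rdname libsize_correlation_filter
#' @return \code{libsize_correlation}: named numeric vector of per-transcript
#'   Pearson correlations with log2 library size (0 for constant transcripts).
#' @export
libsize_correlation <- function(norm) {
  x <- log2(norm$libsizes)
  r <- suppressWarnings(as.vector(stats::cor(t(norm$values), x)))
  r[is.na(r)] <- 0
  names(r) <- rownames(norm$values)
  r
}

#' Per-transcript QC table
#'
#' Total counts, expressed-sample counts and library-size correlation per
#' transcript; the table behind the \code{qc} command-line subcommand.
#' @param counts Integer count matrix.
#' @return data.frame: transcript_id, total_count, n_expressed, libsize_cor.
#' @export
qc_table <- function(counts) {
  norm <- normalize_cpm(counts)
  data.frame(transcript_id = rownames(counts),
             total_count = rowSums(counts),
             n_expressed = rowSums(counts > 0),
             libsize_cor = unname(libsize_correlation(norm)),
             stringsAsFactors = FALSE)
}
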