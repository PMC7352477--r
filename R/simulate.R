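#' Configuration for the synthetic platelet-RNA cohort generator
#'
#' Defines a cohort of spliced-junction count profiles with a planted
#' differential signature and known ground truth. Defaults mirror the sarcoma
#' TEP study design this package models: 3,799 detected spliced transcripts,
#' 57 sarcoma patients and 103 controls (of which 38 flagged former-sarcoma),
#' and a stratified training/evaluation/validation split of 55/52/53 samples.
#'
#' Counts are negative-binomial around \code{mean x libsize factor} with
#' variance \eqn{\mu + \alpha \mu^2} (gamma-Poisson). Baseline transcript
#' abundances are heavy-tailed (log-normal). Planted transcripts get a
#' group-dependent mean shift of \code{effect_log2fc} log2 units, sign random
#' per transcript. A disjoint transcript subset responds to age and gender so
#' confounding is representable; ages are drawn from the same distribution in
#' both classes and gender independently of class, emulating a matched design.
#'
#' @param n_transcripts Number of spliced transcripts (> 0).
#' @param n_sarcoma,n_controls Class sizes (> 0).
#' @param frac_former Fraction of controls flagged former-sarcoma (reporting
#'   stratum only; statistically identical to healthy controls).
#' @param n_de Number of planted differential transcripts (<= n_transcripts).
#' @param effect_log2fc Absolute log2 fold-change of each planted transcript.
#' @param dispersion Negative-binomial dispersion \eqn{\alpha} (> 0).
#' @param libsize_log_mean,libsize_log_sd Log-normal library-size parameters
#'   (natural-log scale of total spliced reads per sample).
#' @param confounder_strength Magnitude (log2 units per SD of age, and per
#'   gender contrast) of confounder effects on a transcript subset disjoint
#'   from the planted signature; 0 disables them.
#' @param series_fractions Length-3 fractions (training, evaluation,
#'   validation) summing to 1.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class \code{"sim_config"}.
#' @export
#' @examples
#' cfg <- sim_config(n_transcripts = 200, n_sarcoma = 12, n_controls = 12,
#'                   n_de = 20, seed = 1)
sim_config <- function(n_transcripts = 3799L,
                       n_sarcoma = 57L,
                       n_controls = 103L,
                       frac_former = 38 / 103,
                       n_de = 400L,
                       effect_log2fc = 1.5,
                       dispersion = 0.2,
                       libsize_log_mean = log(1e6),
                       libsize_log_sd = 0.4,
                       confounder_strength = 0.5,
                       series_fractions = c(55, 52, 53) / 160,
                       seed = 1L) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              n_sarcoma = as.integer(n_sarcoma),
              n_controls = as.integer(n_controls),
              frac_former = frac_former,
              n_de = as.integer(n_de),
              effect_log2fc = effect_log2fc,
              dispersion = dispersion,
              libsize_log_mean = libsize_log_mean,
              libsize_log_sd = libsize_log_sd,
              confounder_strength = confounder_strength,
              series_fractions = series_fractions,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_transcripts <= 0 || cfg$n_sarcoma <= 0 || cfg$n_controls <= 0) {
    stop("all cohort sizes must be positive")
  }
  if (cfg$n_de < 0 || cfg$n_de > cfg$n_transcripts) {
    stop("n_de must lie in [0, n_transcripts]")
  }
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (cfg$frac_former < 0 || cfg$frac_former > 1) stop("frac_former must be in [0, 1]")
  if (length(cfg$series_fractions) != 3L ||
      abs(sum(cfg$series_fractions) - 1) > 1e-9 || any(cfg$series_fractions < 0)) {
    stop("series_fractions must be three non-negative fractions summing to 1")
  }
  invisible(cfg)
}

#' Simulate a platelet-like spliced-RNA cohort with known ground truth
#'
#' Generates a transcripts x samples integer count matrix, a sample
#' annotation table (class, control subtype, age, gender, series) and the
#' planted-signature truth, per the model described in [sim_config()].
#'
#' @param config A [sim_config()] object.
#' @return An object of class \code{"synthetic_cohort"}: a list with
#'   \describe{
#'     \item{counts}{integer matrix, transcripts x samples, with dimnames.}
#'     \item{annotation}{data.frame with columns sample_id, class, subtype,
#'       age, gender, series.}
#'     \item{truth}{data.frame with columns transcript_id, log2fc for the
#'       planted transcripts.}
#'     \item{confounded}{transcript ids carrying age/gender effects.}
#'     \item{balance}{class-wise age/gender balance report (data.frame).}
#'     \item{config}{the generating config.}
#'   }
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_transcripts = 100, n_sarcoma = 10,
#'                                   n_controls = 10, n_de = 10, seed = 7))
#' dim(coh$counts)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  nt <- config$n_transcripts
  n1 <- config$n_sarcoma
  n0 <- config$n_controls
  n <- n1 + n0

  tx_ids <- sprintf("TX%05d", seq_len(nt))
  sample_ids <- sprintf("S%03d", seq_len(n))
  cls <- c(rep("sarcoma", n1), rep("control", n0))

  ann <- with_seed(derive_seed(config$seed, "annotation"), {
    # matched design: same age distribution per class, gender independent
    age <- pmin(85, pmax(18, round(stats::rnorm(n, mean = 58, sd = 12))))
    gender <- ifelse(stats::runif(n) < 0.5, "F", "M")
    n_former <- round(config$frac_former * n0)
    subtype <- rep("active", n)
    former_idx <- n1 + sample.int(n0, n_former)
    subtype[cls == "control"] <- "healthy"
    subtype[former_idx] <- "former"
    data.frame(sample_id = sample_ids, class = cls, subtype = subtype,
               age = age, gender = gender, stringsAsFactors = FALSE)
  })
  ann <- split_series(ann, config$series_fractions,
                      seed = derive_seed(config$seed, "series"))

  gen <- with_seed(derive_seed(config$seed, "counts"), {
    de_idx <- integer(0)
    truth_lfc <- numeric(0)
    conf_idx <- integer(0)
    libsize <- stats::rlnorm(n, config$libsize_log_mean, config$libsize_log_sd)
    # heavy-tailed baseline relative abundances
    w <- stats::rlnorm(nt, meanlog = 0, sdlog = 1.8)
    w <- w / sum(w)
    mu <- outer(w, libsize)                       # nt x n expected counts

    if (config$n_de > 0) {
      de_idx <- sort(sample.int(nt, config$n_de))
      truth_lfc <- config$effect_log2fc * sample(c(-1, 1), config$n_de, replace = TRUE)
      # symmetric half-shift keeps the overall expression level unchanged
      shift <- matrix(1, config$n_de, n)
      shift[, cls == "sarcoma"] <- 2^(truth_lfc / 2)
      shift[, cls == "control"] <- 2^(-truth_lfc / 2)
      mu[de_idx, ] <- mu[de_idx, ] * shift
    }
    if (config$confounder_strength > 0) {
      pool <- setdiff(seq_len(nt), de_idx)
      n_conf <- min(length(pool), max(0L, round(0.1 * nt)))
      conf_idx <- sort(sample(pool, n_conf))
      if (n_conf > 0) {
        half <- n_conf %/% 2
        age_z <- (ann$age - mean(ann$age)) / stats::sd(ann$age)
        g01 <- as.numeric(ann$gender == "F")
        if (half > 0) {
          mu[conf_idx[seq_len(half)], ] <-
            mu[conf_idx[seq_len(half)], , drop = FALSE] *
            2^(config$confounder_strength * matrix(age_z, half, n, byrow = TRUE))
        }
        if (n_conf > half) {
          rest <- conf_idx[(half + 1):n_conf]
          mu[rest, ] <- mu[rest, , drop = FALSE] *
            2^(config$confounder_strength * matrix(g01 - 0.5, length(rest), n, byrow = TRUE))
        }
      }
    }
    m <- matrix(stats::rnbinom(nt * n, mu = mu, size = 1 / config$dispersion),
                nt, n)
    dimnames(m) <- list(tx_ids, sample_ids)
    storage.mode(m) <- "integer"
    list(counts = m, de_idx = de_idx, truth_lfc = truth_lfc, conf_idx = conf_idx)
  })
  counts <- gen$counts
  de_idx <- gen$de_idx
  truth_lfc <- gen$truth_lfc
  conf_idx <- gen$conf_idx

  truth <- data.frame(transcript_id = tx_ids[de_idx],
                      log2fc = truth_lfc, stringsAsFactors = FALSE)
  balance <- do.call(rbind, lapply(split(ann, ann$class), function(d) {
    data.frame(class = d$class[1], n = nrow(d), median_age = stats::median(d$age),
               frac_female = mean(d$gender == "F"), stringsAsFactors = FALSE)
  }))
  rownames(balance) <- NULL

  structure(list(counts = counts, annotation = ann, truth = truth,
                 confounded = tx_ids[conf_idx], balance = balance,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TEP cohort: %d transcripts x %d samples (%d sarcoma, %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$annotation$class == "sarcoma"),
              sum(x$annotation$class == "control")))
  cat(sprintf("  planted signature: %d transcripts, |log2FC| = %g\n",
              nrow(x$truth), x$config$effect_log2fc))
  cat("  series:", paste(sprintf("%s=%d", names(table(x$annotation$series)),
                                 table(x$annotation$series)), collapse = " "), "\n")
  invisible(x)
}

#' Stratified training/evaluation/validation split
#'
#' Assigns each sample to exactly one series, stratified by class so class
#' proportions are preserved per series within rounding (largest-remainder
#' apportionment within each class). Deterministic given the seed.
#'
#' @param annotation Sample annotation data.frame with a \code{class} column.
#' @param fractions Length-3 non-negative fractions (training, evaluation,
#'   validation) summing to 1.
#' @param seed Integer seed.
#' @return The annotation with a \code{series} column
#'   (training/evaluation/validation).
#' @export
split_series <- function(annotation, fractions, seed) {
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3L || any(fractions < 0)) {
    stop("fractions must be three non-negative values summing to 1")
  }
  if (nrow(annotation) == 0 || any(table(factor(annotation$class)) == 0)) {
    stop("each class must contain at least one sample")
  }
  series_names <- c("training", "evaluation", "validation")
  annotation$series <- NA_character_
  with_seed(seed, {
    for (cl in unique(annotation$class)) {
      idx <- which(annotation$class == cl)
      nk <- length(idx)
      quota <- fractions * nk
      base <- floor(quota)
      rem <- quota - base
      short <- nk - sum(base)
      if (short > 0) {
        base[order(rem, decreasing = TRUE)[seq_len(short)]] <-
          base[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
      }
      assign_vec <- rep(series_names, times = base)
      annotation$series[idx] <- sample(assign_vec)
    }
  })
  annotation
}
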