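#' Per-transcript one-way ANOVA between sarcoma and control
#'
#' Fixed-effects one-way ANOVA of normalized expression against the class
#' label, computed row-wise in closed form for speed (the swarm re-runs this
#' for every particle). With two groups the F statistic equals the square of
#' the pooled-variance two-sample t statistic, with p from F(1, n - 2).
#' Transcripts constant across all samples (or any zero within-group variance
#' with equal group means) get F = 0, p = 1.
#'
#' @param norm A [normalize_cpm()] object (or any \code{tep_norm}).
#' @param labels Character/factor class per sample, exactly 2 levels, at
#'   least 2 samples each.
#' @return data.frame of class \code{"tep_differential"}: transcript_id, F,
#'   p, q (BH-adjusted), mean_diff (sarcoma - control in log2 units; for
#'   generic labels, first level minus second).
#' @export
anova_per_transcript <- function(norm, labels) {
  v <- norm$values
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("exactly 2 classes required, got: ", paste(lev, collapse = ", "))
  # report sarcoma - control when those labels are used
  if (setequal(lev, c("sarcoma", "control"))) lev <- c("sarcoma", "control")
  g1 <- labels == lev[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  if (n1 < 2 || n2 < 2) stop("each class needs at least 2 samples")

  m1 <- rowMeans(v[, g1, drop = FALSE])
  m2 <- rowMeans(v[, !g1, drop = FALSE])
  grand <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ssw <- (n1 - 1) * row_vars(v[, g1, drop = FALSE]) +
         (n2 - 1) * row_vars(v[, !g1, drop = FALSE])
  msw <- ssw / (n - 2)
  f <- ifelse(msw > 0, ssb / msw, ifelse(ssb > 0, Inf, 0))
  p <- ifelse(is.infinite(f), 0, stats::pf(f, 1, n - 2, lower.tail = FALSE))
  p[f == 0] <- 1

  res <- data.frame(transcript_id = rownames(v), F = f, p = p,
                    q = bh_fdr(p), mean_diff = m1 - m2,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("tep_differential", "data.frame")
  res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin, validating wrapper over \code{stats::p.adjust(method = "BH")}:
#' monotone, capped at 1, input order preserved.
#' @param pvalues Numeric p-values in \code{[0, 1]}.
#' @return Adjusted q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Select transcripts below an FDR threshold
#'
#' Strict inequality \code{q < threshold} (matching the "FDR < 0.05"
#' convention), returned sorted by ascending q, then ascending p, then
#' transcript id — a deterministic ranking reused for panel construction.
#'
#' @param result A [anova_per_transcript()] table.
#' @param threshold q cutoff in \code{(0, 1]}.
#' @return Character vector of selected transcript ids, ranked.
#' @export
select_by_fdr <- function(result, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  hit <- result[result$q < threshold, , drop = FALSE]
  hit <- hit[order(hit$q, hit$p, hit$transcript_id), , drop = FALSE]
  hit$transcript_id
}

#' Write a differential table as TSV
#' @param result A [anova_per_transcript()] table.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_differential <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
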