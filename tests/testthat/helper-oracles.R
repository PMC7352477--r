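# Independent brute-force oracles used to verify the package's statistics.
# These deliberately re-derive each quantity from its definition and share no
# code with the implementation under test.

# Benjamini-Hochberg step-up by direct minimisation over the definition:
# q_(k) = min_{j >= k} m * p_(j) / j, capped at 1, mapped back to input order.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- vapply(seq_len(m), function(k) {
    min(1, min(m * ps[k:m] / (k:m)))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# pooled-variance two-sample t statistic from first principles
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# AUC as the area under the empirical ROC polygon by trapezoidal integration
auc_trapezoid <- function(scores, pos) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

# AUC by explicit concordant-pair counting (ties count one half)
auc_pairs_explicit <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# two-sided Fisher exact p by full enumeration of tables with fixed margins,
# using the probability-ordering rule (as fisher.test does)
fisher_enumerate <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  k_obs <- tab[1, 1]
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(k_obs, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# deterministic small planted cohort for classifier tests
tiny_cohort <- function(seed = 1, n_transcripts = 400, n_per_class = 24,
                        n_de = 40, effect = 2, fractions = c(0.4, 0.3, 0.3)) {
  simulate_cohort(sim_config(
    n_transcripts = n_transcripts, n_sarcoma = n_per_class,
    n_controls = n_per_class, n_de = n_de, effect_log2fc = effect,
    series_fractions = fractions, seed = seed))
}

# small swarm budget for fast end-to-end runs
tiny_config <- function(seed = 1, n_particles = 8, n_iterations = 2,
                        n_ranked_max = 400) {
  run_config(n_particles = n_particles, n_iterations = n_iterations,
             boot_resamples = 200,
             bounds = list(libsize_cor = c(-0.1, 1), fdr = c(1e-5, 1),
                           cor = c(0.5, 1), n_ranked = c(20, n_ranked_max)),
             seed = seed)
}

norm_of <- function(cohort, min_total = 30, min_samples = 3) {
  normalize_cpm(filter_low_coverage(cohort$counts, min_total, min_samples))
}

series_split <- function(cohort, min_total = 30, min_samples = 3) {
  norm <- norm_of(cohort, min_total, min_samples)
  ann <- cohort$annotation
  out <- list()
  for (s in c("training", "evaluation", "validation")) {
    ids <- ann$sample_id[ann$series == s]
    out[[s]] <- list(norm = subset_norm_test(norm, ids),
                     labels = ann$class[ann$series == s])
  }
  out
}

# standalone sample subsetter so helpers don't reach into internals
subset_norm_test <- function(norm, samples) {
  structure(list(values = norm$values[, samples, drop = FALSE],
                 libsizes = norm$libsizes[samples]), class = "tep_norm")
}
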