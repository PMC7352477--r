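#' ROC AUC by Mann-Whitney pair counting, with bootstrap CI
#'
#' AUC is the fraction of (sarcoma, control) score pairs ranked concordantly,
#' ties counting one half — the Mann-Whitney U definition, computed via
#' mid-ranks. The 95% CI is a class-stratified percentile bootstrap
#' (resampling scores within each class), seeded and truncated to
#' \code{[0, 1]}.
#'
#' @param scores Numeric scores (higher = more sarcoma-like).
#' @param labels Class labels; \code{"sarcoma"} (or 1/TRUE) is the positive
#'   class.
#' @param ci Compute the bootstrap CI? Default TRUE.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level, default 0.95.
#' @return List: \code{auc}, and if \code{ci} \code{ci_lo}, \code{ci_hi},
#'   \code{n_boot}.
#' @export
roc_auc <- function(scores, labels, ci = TRUE, n_boot = 2000L, seed = 1L,
                    conf = 0.95) {
  pos <- as_positive(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute an AUC")
  auc <- auc_pair(scores, pos)
  out <- list(auc = auc)
  if (ci) {
    sp <- scores[pos]
    sn <- scores[!pos]
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        auc_pair(c(sample(sp, n1, replace = TRUE), sample(sn, n0, replace = TRUE)),
                 c(rep(TRUE, n1), rep(FALSE, n0)))
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
    out$ci_lo <- max(0, qs[1])
    out$ci_hi <- min(1, qs[2])
    out$n_boot <- as.integer(n_boot)
  }
  out
}

as_positive <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "sarcoma"
  } else as.logical(labels)
}

# mid-rank Mann-Whitney AUC
auc_pair <- function(scores, pos) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' Sensitivity/1-specificity at every distinct score threshold, for curve
#' export and trapezoidal-area cross-checks.
#' @inheritParams roc_auc
#' @return data.frame: threshold, sensitivity, fpr (descending thresholds).
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  data.frame(threshold = th,
             sensitivity = vapply(th, function(t) mean(scores[pos] >= t), numeric(1)),
             fpr = vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)))
}

#' Confusion table and summary rates at a TEP-score cutoff
#'
#' Applies the [classify()] tie rule (score >= cutoff is sarcoma), tabulates
#' the 2x2 cross-table and reports sensitivity, specificity and accuracy.
#' Rates are kept at full precision; \code{*_pct} fields carry the
#' whole-percent display rounding used in reporting. A series with no
#' sarcoma (or no control) samples yields NA for the undefined rate, with a
#' warning.
#'
#' @inheritParams roc_auc
#' @param cutoff Decision cutoff in \code{(0, 1)}.
#' @return List of class \code{"confusion_report"}: TP, FN, TN, FP,
#'   sensitivity, specificity, accuracy (fractions), sensitivity_pct,
#'   specificity_pct, accuracy_pct (whole percents), cutoff.
#' @export
confusion_report <- function(scores, labels, cutoff = 0.5) {
  pos <- as_positive(labels)
  call_sarc <- classify(scores, cutoff) == "sarcoma"
  tp <- sum(pos & call_sarc)
  fn <- sum(pos & !call_sarc)
  tn <- sum(!pos & !call_sarc)
  fp <- sum(!pos & call_sarc)
  if (tp + fn == 0 || tn + fp == 0) {
    warning("a class is empty; its rate is NA")
  }
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(scores)
  structure(list(TP = tp, FN = fn, TN = tn, FP = fp,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 sensitivity_pct = round(100 * sens),
                 specificity_pct = round(100 * spec),
                 accuracy_pct = round(100 * acc),
                 cutoff = cutoff),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("2x2 cross-table at TEP-score cutoff %.2f\n", x$cutoff))
  cat(sprintf("              called sarcoma  called control\n"))
  cat(sprintf("  sarcoma     %14d  %14d\n", x$TP, x$FN))
  cat(sprintf("  control     %14d  %14d\n", x$FP, x$TN))
  cat(sprintf("  sensitivity %s%%  specificity %s%%  accuracy %s%%\n",
              x$sensitivity_pct, x$specificity_pct, x$accuracy_pct))
  invisible(x)
}

#' Reconstruct a confusion table from class sizes and per-class rates
#'
#' Given the printed class sizes and whole-percent sensitivity/specificity of
#' a series, recovers the integer 2x2 table (counts are the rounded products)
#' and the implied accuracy — the arithmetic used to cross-check published
#' cross-tables.
#'
#' @param n_sarcoma,n_controls Integer class sizes.
#' @param sensitivity,specificity Rates as fractions (e.g. 0.81).
#' @return A \code{confusion_report} built from the reconstructed counts.
#' @export
confusion_from_rates <- function(n_sarcoma, n_controls, sensitivity, specificity) {
  tp <- round(sensitivity * n_sarcoma)
  tn <- round(specificity * n_controls)
  scores <- c(rep(1, tp), rep(0, n_sarcoma - tp), rep(0, tn), rep(1, n_controls - tn))
  labels <- c(rep("sarcoma", n_sarcoma), rep("control", n_controls))
  confusion_report(scores, labels, cutoff = 0.5)
}

#' Shuffled-class-label control (permutation null)
#'
#' For each shuffle, the class labels of the training + evaluation samples
#' are permuted, the full swarm optimization is re-run on the shuffled
#' labels, and the locked panel is scored on the untouched, truly-labeled
#' validation series. Reports the median and IQR of the null validation
#' AUCs. A reduced particle budget may be passed via \code{config}.
#'
#' @param norm_train,labels_train,norm_eval,labels_eval,config As in
#'   [pso_optimize()].
#' @param norm_valid,labels_valid Fixed validation series.
#' @param n_shuffles Number of label permutations (>= 2).
#' @param seed Integer seed.
#' @return List: \code{median_auc}, \code{iqr}, \code{aucs}.
#' @export
shuffled_label_control <- function(norm_train, labels_train, norm_eval,
                                   labels_eval, norm_valid, labels_valid,
                                   config, n_shuffles = 1000L, seed = 1L) {
  stopifnot(n_shuffles >= 2)
  n_tr <- length(labels_train)
  lab_all <- c(as.character(labels_train), as.character(labels_eval))
  aucs <- vapply(seq_len(n_shuffles), function(b) {
    perm <- with_seed(derive_seed(seed, paste0("shuffle", b)), sample(lab_all))
    lt <- perm[seq_len(n_tr)]
    le <- perm[(n_tr + 1):length(perm)]
    if (length(unique(lt)) < 2 || length(unique(le)) < 2) return(0.5)
    res <- pso_optimize(norm_train, lt, norm_eval, le, config)
    s <- tep_score(res$panel, norm_valid, series = "validation")
    unname(roc_auc(s, labels_valid, ci = FALSE)$auc)
  }, numeric(1))
  list(median_auc = stats::median(aucs), iqr = stats::IQR(aucs), aucs = aucs)
}

#' Shuffled-training control (split robustness)
#'
#' For each iteration, the training/evaluation split is randomly re-drawn
#' among the pooled training + evaluation samples (class labels intact,
#' original series sizes preserved), the swarm optimization is re-run, and
#' the locked panel is scored on the fixed validation series. This measures
#' robustness of the pipeline to the particular split, as opposed to the
#' chance-level label-shuffle null.
#'
#' @inheritParams shuffled_label_control
#' @param n_iter Number of random re-splits (>= 2).
#' @return List: \code{median_auc}, \code{iqr}, \code{aucs}.
#' @export
shuffled_training_control <- function(norm_train, labels_train, norm_eval,
                                      labels_eval, norm_valid, labels_valid,
                                      config, n_iter = 1000L, seed = 1L) {
  stopifnot(n_iter >= 2)
  lab_all <- c(as.character(labels_train), as.character(labels_eval))
  ids_all <- c(colnames(norm_train$values), colnames(norm_eval$values))
  norm_all <- structure(list(
    values = cbind(norm_train$values, norm_eval$values),
    libsizes = c(norm_train$libsizes, norm_eval$libsizes)), class = "tep_norm")
  n_tr <- length(labels_train)
  aucs <- vapply(seq_len(n_iter), function(b) {
    idx <- with_seed(derive_seed(seed, paste0("resplit", b)),
                     sample(length(ids_all)))
    tr <- idx[seq_len(n_tr)]
    ev <- idx[(n_tr + 1):length(idx)]
    lt <- lab_all[tr]
    le <- lab_all[ev]
    if (length(unique(lt)) < 2 || length(unique(le)) < 2) return(0.5)
    res <- pso_optimize(subset_norm(norm_all, samples = ids_all[tr]), lt,
                        subset_norm(norm_all, samples = ids_all[ev]), le, config)
    s <- tep_score(res$panel, norm_valid, series = "validation")
    unname(roc_auc(s, labels_valid, ci = FALSE)$auc)
  }, numeric(1))
  list(median_auc = stats::median(aucs), iqr = stats::IQR(aucs), aucs = aucs)
}

#' Venn partition of transcript signatures
#'
#' Exact cell counts of every non-empty intersection/exclusion region of 2
#' or 3 named transcript sets, plus per-set unique counts and fractions
#' formatted as in signature-overlap reporting ("unique/total (pct\%)").
#'
#' @param sets Named list of 2 or 3 character vectors of transcript ids.
#' @return List of class \code{"venn_partition"}: \code{cells} (named counts
#'   keyed by membership pattern, e.g. \code{"A&B"}), \code{unique} (per-set
#'   unique counts), \code{unique_fraction}, \code{formatted}, \code{total}
#'   (size of the union).
#' @export
signature_overlap <- function(sets) {
  k <- length(sets)
  if (!k %in% c(2L, 3L)) stop("signature_overlap needs 2 or 3 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0)) warning("empty signature set(s); their cells are 0")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  patterns <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "&"))
  cells <- table(patterns)
  cells <- stats::setNames(as.integer(cells), names(cells))
  uniq <- vapply(names(sets), function(nm) sum(patterns == nm), integer(1))
  totals <- lengths(sets)
  frac <- ifelse(totals > 0, uniq / totals, NA_real_)
  formatted <- sprintf("%d/%d (%d%%)", uniq, totals, round(100 * frac))
  names(formatted) <- names(sets)
  structure(list(cells = cells, unique = uniq, unique_fraction = frac,
                 formatted = formatted, total = length(universe)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Signature overlap (", x$total, " transcripts in union)\n", sep = "")
  for (nm in names(x$cells)) cat(sprintf("  %-12s %d\n", nm, x$cells[[nm]]))
  cat("  unique per set:", paste(names(x$formatted), x$formatted,
                                 sep = ": ", collapse = "; "), "\n")
  invisible(x)
}
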