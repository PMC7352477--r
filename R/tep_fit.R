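#' Fit the swarm-optimized TEP-score classifier
#'
#' The package's main fitting function. Takes a spliced-junction count
#' matrix and a sample annotation carrying the
#' training/evaluation/validation series assignment, then:
#' \enumerate{
#'   \item filters low-coverage transcripts and normalizes to log2-CPM;
#'   \item swarm-optimizes the four panel-selection hyperparameters on the
#'     training series with evaluation-series AUC as fitness
#'     ([pso_optimize()]);
#'   \item locks the winning biomarker panel;
#'   \item scores all three series with the locked panel, reporting ROC/AUC
#'     with bootstrap CI and the 2x2 cross-table at the cutoff;
#'   \item optionally re-assesses the training series by leave-one-out
#'     cross-validation with the locked particle parameters.
#' }
#' Validation samples never enter selection, fitting, or optimization.
#'
#' @param counts Integer count matrix (transcripts x samples), e.g. from
#'   [read_counts()] or [simulate_cohort()].
#' @param annotation Sample annotation data.frame with columns
#'   \code{sample_id}, \code{class}, \code{series} (see [read_annotation()]).
#' @param config A [run_config()]; defaults to the published settings
#'   (100 particles, 10 iterations, published bounds, cutoff 0.5).
#' @param loocv Also run leave-one-out cross-validation on the training
#'   series? Costs one panel refit per training sample. Default FALSE.
#' @return An object of class \code{"tep_fit"} with components
#'   \code{panel} (locked [build_panel()] artifact), \code{params} (best
#'   particle), \code{trace} (swarm fitness trace), \code{scores} (named
#'   list per series), \code{reports} (per-series AUC + confusion),
#'   \code{loocv_scores} (if requested), \code{annotation}, \code{config}.
#' @seealso [predict.tep_fit()], [summary.tep_fit()], [plot.tep_fit()]
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_transcripts = 300, n_sarcoma = 24,
#'                                   n_controls = 24, n_de = 30,
#'                                   effect_log2fc = 2, seed = 1))
#' cfg <- run_config(n_particles = 8, n_iterations = 2, boot_resamples = 200)
#' fit <- tep_fit(coh$counts, coh$annotation, cfg)
#' fit
tep_fit <- function(counts, annotation, config = run_config(), loocv = FALSE) {
  stopifnot(inherits(config, "run_config"))
  annotation <- check_annotation(annotation, counts)
  annotation <- annotation[match(colnames(counts), annotation$sample_id), ]

  filtered <- filter_low_coverage(counts, config$min_total_reads,
                                  config$min_samples_expressed)
  log_stage("preprocess", n_in = nrow(counts), n_kept = nrow(filtered),
            min_total = config$min_total_reads,
            min_samples = config$min_samples_expressed)
  norm <- normalize_cpm(filtered)

  series_of <- function(s) annotation$sample_id[annotation$series == s]
  labels_of <- function(s) annotation$class[annotation$series == s]
  norm_tr <- subset_norm(norm, samples = series_of("training"))
  norm_ev <- subset_norm(norm, samples = series_of("evaluation"))
  norm_va <- subset_norm(norm, samples = series_of("validation"))

  res <- pso_optimize(norm_tr, labels_of("training"),
                      norm_ev, labels_of("evaluation"), config)
  log_stage("swarm", particles = config$n_particles,
            iterations = config$n_iterations,
            best_eval_auc = round(res$fitness, 4),
            panel_size = length(res$panel$transcripts))

  series_norm <- list(training = norm_tr, evaluation = norm_ev,
                      validation = norm_va)
  scores <- list()
  reports <- list()
  for (s in names(series_norm)) {
    if (ncol(series_norm[[s]]$values) == 0) next
    sc <- tep_score(res$panel, series_norm[[s]], series = s)
    lab <- labels_of(s)
    rep_s <- list(scores = sc, labels = lab)
    if (length(unique(lab)) == 2) {
      rep_s <- c(rep_s,
                 roc_auc(sc, lab, n_boot = config$boot_resamples,
                         seed = derive_seed(config$seed, paste0("boot-", s))),
                 list(confusion = confusion_report(sc, lab, config$cutoff)))
    }
    scores[[s]] <- sc
    reports[[s]] <- rep_s
  }

  loocv_scores <- NULL
  if (loocv) {
    loocv_scores <- loocv(norm_tr, labels_of("training"), res$params)
    reports$loocv <- c(list(scores = loocv_scores, labels = labels_of("training")),
                       roc_auc(loocv_scores, labels_of("training"),
                               n_boot = config$boot_resamples,
                               seed = derive_seed(config$seed, "boot-loocv")),
                       list(confusion = confusion_report(loocv_scores,
                                                         labels_of("training"),
                                                         config$cutoff)))
  }

  structure(list(panel = res$panel, params = res$params, trace = res$trace,
                 fitness = res$fitness, scores = scores, reports = reports,
                 loocv_scores = loocv_scores, annotation = annotation,
                 config = config, norm = norm),
            class = "tep_fit")
}

#' @export
print.tep_fit <- function(x, ...) {
  cat("Swarm-optimized TEP-score classifier\n")
  cat(sprintf("  panel: %d transcripts (locked), RBF SVM\n",
              length(x$panel$transcripts)))
  cat(sprintf("  best particle: libsize_cor_lo=%.3f fdr=%.3g cor=%.3f n_ranked=%d\n",
              x$params$libsize_cor_lo, x$params$fdr_threshold,
              x$params$cor_threshold, x$params$n_ranked))
  for (s in names(x$reports)) {
    r <- x$reports[[s]]
    if (!is.null(r$auc)) {
      cat(sprintf("  %-11s AUC %.3f (95%% CI %.3f-%.3f), accuracy %d%%\n",
                  s, r$auc, r$ci_lo, r$ci_hi, r$confusion$accuracy_pct))
    }
  }
  invisible(x)
}

#' Summarize a fitted TEP-score classifier
#' @param object A [tep_fit()] object.
#' @param ... Unused.
#' @return The object, invisibly; prints per-series cross-tables.
#' @export
summary.tep_fit <- function(object, ...) {
  print(object)
  for (s in names(object$reports)) {
    r <- object$reports[[s]]
    if (!is.null(r$confusion)) {
      cat("\n--", s, "series --\n")
      print(r$confusion)
    }
  }
  invisible(object)
}

#' Panel membership of a fitted TEP-score classifier
#' @param object A [tep_fit()] object.
#' @param ... Unused.
#' @return data.frame: transcript_id, train_mean, train_sd (the frozen
#'   normalization reference of the locked panel).
#' @export
coef.tep_fit <- function(object, ...) {
  p <- object$panel
  data.frame(transcript_id = p$transcripts,
             train_mean = unname(p$center), train_sd = unname(p$scale),
             stringsAsFactors = FALSE)
}

#' Score new samples with a fitted TEP-score classifier
#'
#' @param object A [tep_fit()] object (its panel is locked).
#' @param counts Count matrix of new samples (transcripts x samples); must
#'   contain every panel transcript. Defaults to re-scoring the fitted data.
#' @param type \code{"score"} (TEP-scores in \code{[0, 1]}) or
#'   \code{"class"} (sarcoma/control at the cutoff).
#' @param cutoff Decision cutoff; defaults to the fitted config's.
#' @param ... Unused.
#' @return Named vector of scores or class calls.
#' @export
predict.tep_fit <- function(object, counts = NULL,
                            type = c("score", "class"), cutoff = NULL, ...) {
  type <- match.arg(type)
  cutoff <- cutoff %||% object$config$cutoff
  norm <- if (is.null(counts)) object$norm else normalize_cpm(counts)
  s <- tep_score(object$panel, norm)
  if (type == "class") classify(s, cutoff) else s
}

#' Diagnostic plots for a fitted TEP-score classifier
#'
#' Two base-graphics panels: the swarm fitness trace (per-iteration best and
#' global best evaluation AUC) and the ROC curves of the available series.
#' @param x A [tep_fit()] object.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, \code{x}.
#' @export
plot.tep_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  agg <- stats::aggregate(eval_auc ~ iteration, data = x$trace, FUN = max)
  gb <- stats::aggregate(gbest_auc ~ iteration, data = x$trace, FUN = max)
  graphics::plot(agg$iteration, agg$eval_auc, type = "b", pch = 16,
                 xlab = "swarm iteration", ylab = "evaluation AUC",
                 ylim = c(0.4, 1), main = "PSO fitness trace", ...)
  graphics::lines(gb$iteration, gb$gbest_auc, lty = 2)
  graphics::legend("bottomright", c("iteration best", "global best"),
                   lty = c(1, 2), pch = c(16, NA), bty = "n")
  cols <- c(training = "grey40", evaluation = "firebrick", validation = "royalblue")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "false positive rate", ylab = "sensitivity",
                 main = "ROC")
  for (s in intersect(names(cols), names(x$reports))) {
    r <- x$reports[[s]]
    if (is.null(r$auc)) next
    rc <- roc_curve(r$scores, r$labels)
    graphics::lines(rc$fpr, rc$sensitivity, col = cols[[s]], lwd = 2)
  }
  graphics::legend("bottomright", names(cols), col = cols, lwd = 2, bty = "n")
  invisible(x)
}
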