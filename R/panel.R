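#' The four swarm-tuned panel-selection hyperparameters
#'
#' One "particle" of the swarm: the library-size correlation floor, the FDR
#' threshold, the absolute label-correlation threshold, and the number of
#' top-ranked transcripts retained.
#'
#' @param libsize_cor_lo Lower bound of the library-size correlation filter
#'   (upper bound is fixed at 1.0).
#' @param fdr_threshold q-value cutoff for differential selection.
#' @param cor_threshold Minimum absolute point-biserial label correlation.
#' @param n_ranked Number of top-ranked transcripts to keep (integer >= 1).
#' @return An object of class \code{"particle_params"}.
#' @export
particle_params <- function(libsize_cor_lo = -0.1, fdr_threshold = 0.05,
                            cor_threshold = 0.5, n_ranked = 1000L) {
  stopifnot(n_ranked >= 1)
  structure(list(libsize_cor_lo = libsize_cor_lo,
                 fdr_threshold = fdr_threshold,
                 cor_threshold = cor_threshold,
                 n_ranked = as.integer(round(n_ranked))),
            class = "particle_params")
}

#' Point-biserial correlation of each transcript with the class label
#'
#' Pearson correlation between normalized expression and the 0/1 label
#' indicator (sarcoma = 1). Zero-variance transcripts are assigned 0.
#'
#' @param norm A \code{tep_norm} object.
#' @param labels Class labels, exactly two levels with >= 2 samples each.
#' @return Named numeric vector of correlations.
#' @export
label_correlation <- function(norm, labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("exactly 2 classes required")
  y <- if ("sarcoma" %in% lev) as.numeric(labels == "sarcoma") else as.numeric(labels == lev[1])
  if (min(table(labels)) < 2) stop("each class needs at least 2 samples")
  r <- suppressWarnings(as.vector(stats::cor(t(norm$values), y)))
  r[is.na(r)] <- 0
  names(r) <- rownames(norm$values)
  r
}

# Platt sigmoid P(sarcoma | f) = 1 / (1 + exp(a f + b)), fitted by Newton
# iterations on the cross-entropy with Platt's smoothed targets; deterministic.
platt_fit <- function(f, y01, max_iter = 100L, tol = 1e-10) {
  n1 <- sum(y01 == 1)
  n0 <- sum(y01 == 0)
  t_hi <- (n1 + 1) / (n1 + 2)
  t_lo <- 1 / (n0 + 2)
  t <- ifelse(y01 == 1, t_hi, t_lo)
  a <- 0
  b <- log((n0 + 1) / (n1 + 1))
  for (it in seq_len(max_iter)) {
    z <- a * f + b
    p <- 1 / (1 + exp(z))          # P(target class)
    # gradient of sum(-t*log(p) - (1-t)*log(1-p)) wrt (a, b)
    d <- p - t                      # note dp/dz = -p(1-p) flips sign twice
    g <- c(sum(-d * f), sum(-d))
    w <- pmax(p * (1 - p), 1e-12)
    H <- matrix(c(sum(w * f * f), sum(w * f), sum(w * f), sum(w)), 2, 2)
    H <- H + diag(1e-12, 2)
    step <- solve(H, g)
    a <- a - step[1]
    b <- b - step[2]
    if (max(abs(step)) < tol) break
  }
  c(a = a, b = b)
}

platt_prob <- function(f, ab) 1 / (1 + exp(ab[1] * f + ab[2]))

# RBF decision values from stored support vectors: f(x) = sum_i c_i K(sv_i, x) - rho
rbf_decision <- function(svm_pars, x) {
  sv <- svm_pars$SV
  d2 <- outer(rowSums(sv^2), rowSums(x^2), "+") - 2 * sv %*% t(x)
  d2[d2 < 0] <- 0
  k <- exp(-svm_pars$gamma * d2)
  as.vector(t(k) %*% svm_pars$coefs - svm_pars$rho)
}

#' Build a biomarker panel from the training series
#'
#' Runs the swarm-parameterized selection pipeline on training samples only:
#' library-size correlation filter (\code{[libsize_cor_lo, 1.0]}), ANOVA +
#' BH on the survivors, \code{q < fdr_threshold}, absolute label correlation
#' \code{>= cor_threshold}, ranking by ascending q (ties: p, then transcript
#' id), top \code{n_ranked}; each retained transcript is z-scaled by its
#' training mean/sd and an RBF SVM (C = 1, gamma = 1/panel size) is fitted.
#' Class probabilities come from a Platt sigmoid fitted to the training
#' decision values, so scoring is fully reproducible from the stored panel.
#'
#' Parameter settings that leave no transcript standing yield a panel flagged
#' \code{degenerate} (scored at chance downstream) rather than an error, so
#' the swarm can traverse bad regions of the search space.
#'
#' @param norm_train \code{tep_norm} of training samples only.
#' @param labels_train Class labels of the training samples.
#' @param params A [particle_params()] object.
#' @param universe Optional transcript id set to restrict the candidate pool
#'   (used by [restrict_panel()]).
#' @return An object of class \code{"biomarker_panel"} (unlocked).
#' @export
build_panel <- function(norm_train, labels_train, params, universe = NULL) {
  stopifnot(inherits(params, "particle_params"))
  labels_train <- as.character(labels_train)
  if (!is.null(universe)) {
    keep0 <- intersect(rownames(norm_train$values), universe)
    if (length(keep0) == 0) return(degenerate_panel(params))
    norm_train <- subset_norm(norm_train, transcripts = keep0)
  }
  kept <- libsize_correlation_filter(norm_train, lo = params$libsize_cor_lo, hi = 1.0)
  if (length(kept) == 0) return(degenerate_panel(params))
  sub <- subset_norm(norm_train, transcripts = kept)

  diff_tab <- anova_per_transcript(sub, labels_train)
  sel <- select_by_fdr(diff_tab, params$fdr_threshold)
  if (length(sel) == 0) return(degenerate_panel(params))

  r <- label_correlation(sub, labels_train)
  sel <- sel[abs(r[sel]) >= params$cor_threshold]
  if (length(sel) == 0) return(degenerate_panel(params))

  sel <- sel[seq_len(min(params$n_ranked, length(sel)))]

  x <- t(norm_train$values[sel, , drop = FALSE])
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  y <- factor(labels_train, levels = sort(unique(labels_train)))
  gamma <- 1 / ncol(xs)
  fit <- tryCatch(
    e1071::svm(xs, y, kernel = "radial", cost = 1, gamma = gamma, scale = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(degenerate_panel(params))
  svm_pars <- list(SV = unname(fit$SV), coefs = as.vector(fit$coefs),
                   rho = fit$rho, gamma = gamma, cost = 1, kernel = "radial")
  f_train <- rbf_decision(svm_pars, xs)
  y01 <- as.numeric(labels_train == "sarcoma")
  platt <- platt_fit(f_train, y01)

  structure(list(transcripts = sel, center = center, scale = scale_,
                 svm = svm_pars, platt = platt, params = params,
                 degenerate = FALSE, locked = FALSE),
            class = "biomarker_panel")
}

degenerate_panel <- function(params) {
  structure(list(transcripts = character(0), center = NULL, scale = NULL,
                 svm = NULL, platt = NULL, params = params,
                 degenerate = TRUE, locked = FALSE),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate biomarker panel (no transcripts survived selection)\n")
  } else {
    cat(sprintf("Biomarker panel: %d transcripts, RBF SVM (%d SVs), %s\n",
                length(x$transcripts), nrow(x$svm$SV),
                if (x$locked) "LOCKED" else "unlocked"))
    cat(sprintf("  params: libsize_cor_lo=%.3f fdr=%.3g cor=%.3f n_ranked=%d\n",
                x$params$libsize_cor_lo, x$params$fdr_threshold,
                x$params$cor_threshold, x$params$n_ranked))
  }
  invisible(x)
}

#' Lock a biomarker panel
#'
#' After locking, the panel (transcript list, scaling reference, SVM and
#' calibration) is frozen; scoring never mutates it, and only locked panels
#' may be applied to validation or unspecified samples.
#' @param panel A [build_panel()] object.
#' @return The locked panel.
#' @export
lock_panel <- function(panel) {
  stopifnot(inherits(panel, "biomarker_panel"))
  panel$locked <- TRUE
  panel
}

#' Score samples with a biomarker panel (TEP-score)
#'
#' Applies the panel's frozen per-transcript scaling and evaluates the
#' Platt-calibrated SVM probability of class sarcoma; a number in
#' \code{[0, 1]} per sample, deterministic given the panel. A degenerate
#' panel scores every sample at chance (0.5).
#'
#' The training/evaluation/validation locking discipline is enforced here:
#' an unlocked panel may only score training or evaluation samples; scoring
#' validation (or unspecified) samples requires a locked panel.
#'
#' @param panel A \code{biomarker_panel}.
#' @param norm \code{tep_norm} holding the samples to score; must contain
#'   every panel transcript.
#' @param series Which series the samples belong to: \code{"training"},
#'   \code{"evaluation"}, \code{"validation"} or \code{"unknown"} (default).
#' @return Named numeric vector of TEP-scores in \code{[0, 1]}.
#' @export
tep_score <- function(panel, norm,
                      series = c("unknown", "training", "evaluation", "validation")) {
  stopifnot(inherits(panel, "biomarker_panel"))
  series <- match.arg(series)
  if (!panel$locked && !series %in% c("training", "evaluation")) {
    stop("unlocked panel may only score training/evaluation samples; ",
         "lock_panel() before scoring ", series, " samples")
  }
  if (panel$degenerate) {
    s <- rep(0.5, ncol(norm$values))
    names(s) <- colnames(norm$values)
    return(s)
  }
  missing_tx <- setdiff(panel$transcripts, rownames(norm$values))
  if (length(missing_tx)) {
    stop("panel transcript(s) absent from data: ",
         paste(utils::head(missing_tx, 5), collapse = ", "))
  }
  x <- t(norm$values[panel$transcripts, , drop = FALSE])
  xs <- sweep(sweep(x, 2, panel$center), 2, panel$scale, "/")
  f <- rbf_decision(panel$svm, xs)
  s <- platt_prob(f, panel$platt)
  s <- pmin(1, pmax(0, s))
  names(s) <- colnames(norm$values)
  s
}

#' Dichotomize TEP-scores at a cutoff
#'
#' Calls sarcoma iff \code{score >= cutoff}; a tie at exactly the cutoff is
#' called sarcoma (the high-sensitivity direction).
#' @param scores Numeric TEP-scores in \code{[0, 1]}.
#' @param cutoff Decision cutoff in \code{(0, 1)}, default 0.5.
#' @return Character vector \code{"sarcoma"}/\code{"control"}.
#' @export
classify <- function(scores, cutoff = 0.5) {
  stopifnot(cutoff > 0, cutoff < 1)
  ifelse(scores >= cutoff, "sarcoma", "control")
}

#' Leave-one-out cross-validation of the panel pipeline
#'
#' For each training sample, the entire panel-selection pipeline and SVM are
#' re-fitted on the remaining samples (the held-out sample enters no
#' selection or fitting step) and the held-out sample is scored. Folds where
#' a class collapses below 2 samples, or that yield a degenerate panel, are
#' scored at chance (0.5).
#'
#' @param norm_train \code{tep_norm} of training samples.
#' @param labels_train Training class labels (>= 3 per class).
#' @param params A [particle_params()] object.
#' @return Named numeric vector: one honest out-of-fold TEP-score per
#'   training sample.
#' @export
loocv <- function(norm_train, labels_train, params) {
  labels_train <- as.character(labels_train)
  if (min(table(labels_train)) < 3) stop("LOOCV needs at least 3 samples per class")
  n <- ncol(norm_train$values)
  scores <- numeric(n)
  names(scores) <- colnames(norm_train$values)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    lab_i <- labels_train[keep]
    if (min(table(lab_i)) < 2) {
      scores[i] <- 0.5
      next
    }
    sub <- subset_norm(norm_train, samples = colnames(norm_train$values)[keep])
    p_i <- build_panel(sub, lab_i, params)
    held <- subset_norm(norm_train, samples = colnames(norm_train$values)[i])
    scores[i] <- tep_score(p_i, held, series = "training")
  }
  scores
}

#' Retrain the panel on a restricted transcript universe
#'
#' Re-runs [build_panel()] with the candidate pool intersected with
#' \code{allowed} and the same particle parameters — e.g. to test whether a
#' disease-specific transcript subset performs as well as the full panel.
#'
#' @param panel The original panel (provides the particle parameters).
#' @param allowed Non-empty transcript id set.
#' @param norm_train,labels_train Training data as in [build_panel()].
#' @return A new unlocked \code{biomarker_panel} (degenerate if the
#'   intersection is empty).
#' @export
restrict_panel <- function(panel, allowed, norm_train, labels_train) {
  stopifnot(inherits(panel, "biomarker_panel"), length(allowed) > 0)
  build_panel(norm_train, labels_train, panel$params, universe = allowed)
}

#' Serialize / restore / hash a biomarker panel
#'
#' The panel is a single JSON artifact holding everything needed to
#' reproduce scoring: transcript list, scaling constants, support vectors,
#' kernel parameters, Platt coefficients, particle parameters and the locked
#' flag. A panel restored from JSON scores identically to the in-memory one.
#'
#' @param panel A \code{biomarker_panel}.
#' @param path JSON file path.
#' @return \code{write_panel}: invisibly, \code{path}; \code{read_panel}:
#'   the restored panel; \code{panel_hash}: MD5 digest of the canonical
#'   serialization.
#' @export
write_panel <- function(panel, path) {
  writeLines(panel_json(panel), path)
  invisible(path)
}

panel_json <- function(panel) {
  obj <- list(transcripts = panel$transcripts,
              center = unname(panel$center), scale = unname(panel$scale),
              svm = panel$svm, platt = unname(panel$platt),
              params = unclass(panel$params),
              degenerate = panel$degenerate, locked = panel$locked)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 15, null = "null"))
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path))
  params <- do.call(particle_params, obj$params)
  if (isTRUE(obj$degenerate)) {
    p <- degenerate_panel(params)
    p$locked <- isTRUE(obj$locked)
    return(p)
  }
  center <- obj$center
  names(center) <- obj$transcripts
  scale_ <- obj$scale
  names(scale_) <- obj$transcripts
  svm_pars <- obj$svm
  if (!is.matrix(svm_pars$SV)) {
    svm_pars$SV <- matrix(unlist(svm_pars$SV),
                          nrow = length(svm_pars$coefs), byrow = TRUE)
  }
  structure(list(transcripts = obj$transcripts, center = center, scale = scale_,
                 svm = svm_pars, platt = c(a = obj$platt[1], b = obj$platt[2]),
                 params = params, degenerate = FALSE, locked = isTRUE(obj$locked)),
            class = "biomarker_panel")
}

#' @rdname write_panel
#' @export
panel_hash <- function(panel) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(panel_json(panel), f)
  unname(tools::md5sum(f))
}
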