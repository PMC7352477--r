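norm_mat <- function(v) {
  structure(list(values = v, libsizes = stats::setNames(rep(1e6, ncol(v)),
                                                        colnames(v))),
            class = "tep_norm")
}

test_that("label correlation matches brute-force Pearson and conventions", {
  labels <- rep(c("control", "sarcoma"), each = 3)
  y <- as.numeric(labels == "sarcoma")
  v <- rbind(islabel = y, antilabel = 1 - y, flat = rep(2, 6),
             noisy = c(0.3, -1.2, 0.8, 2.1, 1.7, 0.9))
  colnames(v) <- paste0("S", 1:6)
  r <- label_correlation(norm_mat(v), labels)
  expect_equal(unname(r["islabel"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["antilabel"]), -1, tolerance = 1e-12)
  expect_equal(unname(r["flat"]), 0)
  expect_equal(unname(r["noisy"]), cor(v["noisy", ], y), tolerance = 1e-12)
  expect_error(label_correlation(norm_mat(v), rep("sarcoma", 6)), "2 classes")
})

test_that("panel construction recovers planted transcripts on a strong cohort", {
  coh <- simulate_cohort(sim_config(n_transcripts = 1500, n_sarcoma = 30,
                                    n_controls = 30, n_de = 100,
                                    effect_log2fc = 2,
                                    series_fractions = c(1, 0, 0), seed = 21))
  norm <- norm_of(coh)
  panel <- build_panel(norm, coh$annotation$class,
                       particle_params(-0.1, 0.05, 0.5, 200))
  expect_false(panel$degenerate)
  expect_lte(length(panel$transcripts), 200)
  frac_planted <- mean(panel$transcripts %in% coh$truth$transcript_id)
  expect_gte(frac_planted, 0.8)
})

test_that("impossible particle settings yield a degenerate panel, not an error", {
  coh <- tiny_cohort(seed = 3)
  ser <- series_split(coh)
  panel <- build_panel(ser$training$norm, ser$training$labels,
                       particle_params(0.999, 1e-5, 0.999, 50))
  expect_true(panel$degenerate)
  s <- tep_score(panel, ser$training$norm, series = "training")
  expect_true(all(s == 0.5))
})

test_that("TEP-scores are calibrated probabilities, deterministic and bounded", {
  coh <- tiny_cohort(seed = 4, effect = 3)
  ser <- series_split(coh)
  panel <- build_panel(ser$training$norm, ser$training$labels,
                       particle_params(-0.1, 0.05, 0.5, 100))
  s <- tep_score(panel, ser$training$norm, series = "training")
  expect_true(all(s >= 0 & s <= 1))
  # separable training cohort: every sample on the correct side of 0.5
  expect_true(all((s >= 0.5) == (ser$training$labels == "sarcoma")))
  # duplicated sample columns score identically
  dup <- ser$training$norm
  dup$values <- dup$values[, c(1, 1, 2, 2), drop = FALSE]
  colnames(dup$values) <- c("a", "b", "c", "d")
  dup$libsizes <- dup$libsizes[c(1, 1, 2, 2)]
  sd_ <- tep_score(panel, dup, series = "training")
  expect_equal(unname(sd_["a"]), unname(sd_["b"]))
  expect_equal(unname(sd_["c"]), unname(sd_["d"]))
})

test_that("the manual RBF decision path agrees with e1071", {
  set.seed(30)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- factor(rep(c("control", "sarcoma"), each = 20))
  fit <- e1071::svm(x, y, kernel = "radial", cost = 1, gamma = 1 / 6, scale = FALSE)
  ours <- tepscore:::rbf_decision(list(SV = unname(fit$SV),
                                       coefs = as.vector(fit$coefs),
                                       rho = fit$rho, gamma = 1 / 6), x)
  ref <- c(attr(predict(fit, x, decision.values = TRUE), "decision.values"))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("locking discipline gates validation scoring and freezes the panel", {
  coh <- tiny_cohort(seed = 5)
  ser <- series_split(coh)
  panel <- build_panel(ser$training$norm, ser$training$labels,
                       particle_params(-0.1, 0.5, 0.5, 100))
  expect_error(tep_score(panel, ser$validation$norm, series = "validation"),
               "lock")
  expect_error(tep_score(panel, ser$validation$norm), "lock")
  locked <- lock_panel(panel)
  h0 <- panel_hash(locked)
  for (i in 1:3) {
    invisible(tep_score(locked, ser$validation$norm, series = "validation"))
    invisible(classify(tep_score(locked, ser$evaluation$norm)))
  }
  expect_identical(panel_hash(locked), h0)
  # missing transcript is a hard error naming the transcript
  shrunk <- ser$validation$norm
  drop_tx <- locked$transcripts[1]
  shrunk$values <- shrunk$values[setdiff(rownames(shrunk$values), drop_tx), ]
  expect_error(tep_score(locked, shrunk), drop_tx)
})

test_that("panels are byte-identical across repeated builds and JSON round-trips", {
  coh <- tiny_cohort(seed = 6)
  ser <- series_split(coh)
  pp <- particle_params(-0.1, 0.2, 0.5, 80)
  p1 <- build_panel(ser$training$norm, ser$training$labels, pp)
  p2 <- build_panel(ser$training$norm, ser$training$labels, pp)
  expect_identical(panel_hash(p1), panel_hash(p2))
  f <- withr::local_tempfile(fileext = ".json")
  write_panel(lock_panel(p1), f)
  restored <- read_panel(f)
  s1 <- tep_score(lock_panel(p1), ser$validation$norm, series = "validation")
  s2 <- tep_score(restored, ser$validation$norm, series = "validation")
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("classification applies the documented tie rule and is monotone", {
  expect_equal(classify(c(0.49, 0.50, 0.51), 0.5),
               c("control", "sarcoma", "sarcoma"))
  expect_true(all(classify(runif(20), 1e-9) == "sarcoma"))
  s <- runif(50)
  lo <- classify(s, 0.3)
  hi <- classify(s, 0.7)
  expect_false(any(lo == "control" & hi == "sarcoma"))
  expect_error(classify(0.5, 0), "cutoff")
})

test_that("LOOCV scores every sample without it and reveals overfitting", {
  coh <- simulate_cohort(sim_config(n_transcripts = 300, n_sarcoma = 8,
                                    n_controls = 8, n_de = 0,
                                    series_fractions = c(1, 0, 0), seed = 7))
  norm <- norm_of(coh, min_total = 5, min_samples = 1)
  labels <- coh$annotation$class
  pp <- particle_params(-0.1, 1.0, 0.0, 30)
  cv1 <- loocv(norm, labels, pp)
  cv2 <- loocv(norm, labels, pp)
  expect_length(cv1, 16)
  expect_identical(cv1, cv2)
  # on a null cohort, resubstitution looks good while LOOCV stays near chance
  resub <- tep_score(build_panel(norm, labels, pp), norm, series = "training")
  auc_resub <- roc_auc(resub, labels, ci = FALSE)$auc
  auc_cv <- roc_auc(cv1, labels, ci = FALSE)$auc
  expect_gte(auc_resub, auc_cv - 0.05)
  expect_error(loocv(norm, rep(c("sarcoma", "control"), c(2, 14)), pp),
               "3 samples")
})

test_that("restricted panels honour the allowed universe", {
  coh <- tiny_cohort(seed = 8, effect = 3)
  ser <- series_split(coh)
  pp <- particle_params(-0.1, 0.05, 0.5, 100)
  panel <- build_panel(ser$training$norm, ser$training$labels, pp)
  full <- restrict_panel(panel, rownames(ser$training$norm$values),
                         ser$training$norm, ser$training$labels)
  expect_identical(panel_hash(full), panel_hash(panel))
  one <- restrict_panel(panel, panel$transcripts[1],
                        ser$training$norm, ser$training$labels)
  expect_equal(one$transcripts, panel$transcripts[1])
  none <- restrict_panel(panel, c("NOT_A_TX"),
                         ser$training$norm, ser$training$labels)
  expect_true(none$degenerate)
})
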