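test_that("AUC matches pair-counting on worked examples", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0), ci = FALSE)$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.2, 0.4, 0.6),
                       c("sarcoma", "sarcoma", "control", "control"),
                       ci = FALSE)$auc, 0.5)
  s <- runif(30)
  l <- rep(c("sarcoma", "control"), 15)
  a <- roc_auc(s, l, ci = FALSE)$auc
  l_inv <- ifelse(l == "sarcoma", "control", "sarcoma")
  expect_equal(roc_auc(s, l_inv, ci = FALSE)$auc, 1 - a, tolerance = 1e-12)
  expect_error(roc_auc(s, rep("sarcoma", 30)), "both classes")
})

test_that("pair-counting equals trapezoidal ROC area and explicit enumeration", {
  set.seed(14)
  for (i in 1:100) {
    n1 <- sample(2:15, 1); n0 <- sample(2:15, 1)
    s <- round(runif(n1 + n0), sample(c(1, 2, 6), 1))  # induce ties sometimes
    pos <- c(rep(TRUE, n1), rep(FALSE, n0))
    a <- roc_auc(s, pos, ci = FALSE)$auc
    expect_equal(a, auc_trapezoid(s, pos), tolerance = 1e-12)
    expect_equal(a, auc_pairs_explicit(s, pos), tolerance = 1e-12)
  }
})

test_that("AUC and bootstrap CI agree with pROC on a fixed instance", {
  skip_if_not_installed("pROC")
  set.seed(15)
  s <- c(rnorm(25, 1), rnorm(25))
  l <- rep(c("sarcoma", "control"), each = 25)
  ours <- roc_auc(s, l, n_boot = 2000, seed = 1)
  ref <- pROC::roc(response = l, predictor = s, levels = c("control", "sarcoma"),
                   direction = "<", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_true(ours$ci_lo <= ours$auc && ours$auc <= ours$ci_hi)
  expect_lt(ours$ci_hi - ours$ci_lo, 0.35)
})

test_that("confusion reports reproduce published validation arithmetic", {
  # 17 sarcoma of which 15 called sarcoma; 36 controls of which 31 called control
  scores <- c(rep(0.9, 15), rep(0.1, 2), rep(0.1, 31), rep(0.9, 5))
  labels <- c(rep("sarcoma", 17), rep("control", 36))
  rep_ <- confusion_report(scores, labels, cutoff = 0.5)
  expect_equal(rep_$TP, 15)
  expect_equal(rep_$TN, 31)
  expect_equal(rep_$sensitivity_pct, 88)
  expect_equal(rep_$specificity_pct, 86)
  expect_equal(rep_$accuracy_pct, 87)
  expect_equal(rep_$TP + rep_$FN, 17)
  expect_equal(rep_$TN + rep_$FP, 36)
  expect_equal(rep_$accuracy, (rep_$TP + rep_$TN) / 53)
})

test_that("degenerate confusion tables report NA rates with a warning", {
  expect_warning(r <- confusion_report(rep(1, 4), rep("sarcoma", 4)), "NA")
  expect_equal(r$sensitivity, 1)
  expect_true(is.na(r$specificity))
  r2 <- confusion_report(c(0.1, 0.2, 0.3, 0.4),
                         c("sarcoma", "control", "sarcoma", "control"))
  expect_equal(r2$sensitivity, 0)
  expect_equal(r2$specificity, 1)
})

test_that("confusion identities hold across random reports", {
  set.seed(16)
  for (i in 1:50) {
    n1 <- sample(3:20, 1); n0 <- sample(3:20, 1)
    s <- runif(n1 + n0)
    l <- c(rep("sarcoma", n1), rep("control", n0))
    r <- confusion_report(s, l, cutoff = runif(1, 0.1, 0.9))
    expect_equal(r$TP + r$FN, n1)
    expect_equal(r$TN + r$FP, n0)
    expect_equal(r$accuracy, (r$TP + r$TN) / (n1 + n0))
  }
})

test_that("published cross-tables are recoverable from class sizes and rates", {
  tr <- confusion_from_rates(21, 34, 0.81, 0.88)
  expect_equal(tr$accuracy_pct, 85)
  va <- confusion_from_rates(17, 36, 0.88, 0.86)
  expect_equal(va$accuracy_pct, 87)
  expect_equal(va$TP, 15)
  expect_equal(va$TN, 31)
})

test_that("signature overlap partitions exactly", {
  v <- signature_overlap(list(A = c("1", "2", "3"), B = c("2", "3", "4"),
                              C = c("3", "4", "5")))
  expect_equal(unname(v$cells[["A&B&C"]]), 1)
  expect_equal(unname(v$unique[["A"]]), 1)
  expect_equal(unname(v$unique[["B"]]), 0)
  expect_equal(unname(v$unique[["C"]]), 1)
  expect_equal(v$total, 5)
  expect_equal(sum(v$cells), v$total)

  d <- signature_overlap(list(X = c("a", "b"), Y = c("c"), Z = c("d", "e")))
  expect_false("X&Y&Z" %in% names(d$cells))
  expect_equal(unname(d$unique_fraction), c(1, 1, 1))

  same <- signature_overlap(list(P = c("a", "b"), Q = c("a", "b"),
                                 R = c("a", "b")))
  expect_equal(unname(same$cells[["P&Q&R"]]), 2)
  expect_equal(unname(same$unique_fraction), c(0, 0, 0))
  expect_equal(unname(same$formatted["P"]), "0/2 (0%)")

  expect_warning(signature_overlap(list(A = character(0), B = "x")), "empty")
  expect_error(signature_overlap(list(A = "x")), "2 or 3")
})

test_that("overlap cells always sum to the union size", {
  set.seed(17)
  ids <- sprintf("T%03d", 1:60)
  for (i in 1:200) {
    sets <- list(A = sample(ids, sample(1:40, 1)),
                 B = sample(ids, sample(1:40, 1)),
                 C = sample(ids, sample(1:40, 1)))
    v <- signature_overlap(sets)
    expect_equal(sum(v$cells), length(unique(unlist(sets))))
    expect_true(all(v$unique <= lengths(sets)))
  }
})

test_that("permutation and re-split controls are seeded and well-formed", {
  coh <- tiny_cohort(seed = 18, effect = 2)
  ser <- series_split(coh)
  cfg <- tiny_config(seed = 18, n_particles = 4, n_iterations = 1)
  ctl <- shuffled_label_control(ser$training$norm, ser$training$labels,
                                ser$evaluation$norm, ser$evaluation$labels,
                                ser$validation$norm, ser$validation$labels,
                                cfg, n_shuffles = 2, seed = 7)
  ctl2 <- shuffled_label_control(ser$training$norm, ser$training$labels,
                                 ser$evaluation$norm, ser$evaluation$labels,
                                 ser$validation$norm, ser$validation$labels,
                                 cfg, n_shuffles = 2, seed = 7)
  expect_identical(ctl$aucs, ctl2$aucs)
  expect_length(ctl$aucs, 2)
  expect_gte(ctl$iqr, 0)

  rs <- shuffled_training_control(ser$training$norm, ser$training$labels,
                                  ser$evaluation$norm, ser$evaluation$labels,
                                  ser$validation$norm, ser$validation$labels,
                                  cfg, n_iter = 2, seed = 8)
  rs2 <- shuffled_training_control(ser$training$norm, ser$training$labels,
                                   ser$evaluation$norm, ser$evaluation$labels,
                                   ser$validation$norm, ser$validation$labels,
                                   cfg, n_iter = 2, seed = 8)
  expect_identical(rs$aucs, rs2$aucs)
  expect_gte(rs$iqr, 0)
  expect_true(all(rs$aucs >= 0 & rs$aucs <= 1))
})

test_that("re-splitting training keeps validation performance near the original", {
  coh <- simulate_cohort(sim_config(n_transcripts = 600, n_sarcoma = 30,
                                    n_controls = 30, n_de = 60,
                                    effect_log2fc = 3, seed = 19))
  ser <- series_split(coh)
  cfg <- tiny_config(seed = 19, n_particles = 5, n_iterations = 1)
  base <- pso_optimize(ser$training$norm, ser$training$labels,
                       ser$evaluation$norm, ser$evaluation$labels, cfg)
  base_auc <- roc_auc(tep_score(base$panel, ser$validation$norm,
                                series = "validation"),
                      ser$validation$labels, ci = FALSE)$auc
  rs <- shuffled_training_control(ser$training$norm, ser$training$labels,
                                  ser$evaluation$norm, ser$evaluation$labels,
                                  ser$validation$norm, ser$validation$labels,
                                  cfg, n_iter = 10, seed = 20)
  expect_lt(abs(rs$median_auc - base_auc), 0.1)
})
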