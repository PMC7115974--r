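test_that("the fixed tree applies the CMCT gate then the strict severity rule", {
  expect_equal(fixed_tree_predict("abnormal", 90, 80), 0L)
  expect_equal(fixed_tree_predict("normal", 81, 80), 1L)
  expect_equal(fixed_tree_predict("normal", 80, 80), 0L) # boundary: unfavorable
  expect_equal(fixed_tree_predict(c("normal", "abnormal"), c(100, 100), 80),
               c(1L, 0L))
  expect_error(fixed_tree_predict("NA", 90, 80), "filter")
})

test_that("confusion counts match an element-wise tally", {
  cc <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_equal(unclass(cc), c(TP = 2L, TN = 1L, FP = 0L, FN = 0L))
  cc2 <- confusion(rep(0, 10), rep(c(1, 0), 5))
  expect_equal(unclass(cc2), c(TP = 0L, TN = 5L, FP = 0L, FN = 5L))
  expect_error(confusion(c(1, 0), 1), "equal length")

  set.seed(33)
  preds <- sample(0:1, 50, replace = TRUE)
  truths <- sample(0:1, 50, replace = TRUE)
  cc3 <- confusion(preds, truths)
  # brute-force tally
  tally <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (i in 1:50) {
    cell <- if (preds[i] == 1 && truths[i] == 1) "TP"
            else if (preds[i] == 0 && truths[i] == 0) "TN"
            else if (preds[i] == 1) "FP" else "FN"
    tally[cell] <- tally[cell] + 1L
  }
  expect_equal(unclass(cc3), tally)
})

test_that("metrics are the defining ratios, undefined when denominators vanish", {
  m <- compute_metrics(c(TP = 3, TN = 2, FP = 1, FN = 2))
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 2 / 3)
  expect_length(m$undefined, 0)

  expect_equal(compute_metrics(c(TP = 4, TN = 3, FP = 2, FN = 0))$sensitivity, 1)
  m0 <- compute_metrics(c(TP = 0, TN = 0, FP = 0, FN = 0))
  expect_setequal(m0$undefined, c("accuracy", "sensitivity", "specificity"))
  expect_true(is.na(m0$accuracy))

  # identity: accuracy * (P + N) = sensitivity * P + specificity * N
  set.seed(44)
  for (i in 1:20) {
    cc <- confusion(sample(0:1, 40, TRUE), rep(0:1, each = 20))
    m <- compute_metrics(cc)
    P <- cc[["TP"]] + cc[["FN"]]; N <- cc[["TN"]] + cc[["FP"]]
    expect_equal(m$accuracy * (P + N), m$sensitivity * P + m$specificity * N)
  }
})

test_that("node-1 bounds are the abnormal-CMCT class fractions", {
  cmct <- rep(c("abnormal", "normal", "abnormal", "normal"),
              c(1184, 10000 - 1184, 2949, 10000 - 2949))
  labels <- rep(c(1, 0), c(10000, 10000))
  b <- node1_bounds(cmct, labels = labels)
  expect_equal(b$sens_upper_bound, 0.8816)
  expect_equal(b$spec_lower_bound, 0.2949)

  b2 <- node1_bounds(rep("normal", 10), labels = rep(c(1, 0), 5))
  expect_equal(b2$sens_upper_bound, 1)
  b3 <- node1_bounds(c(rep("normal", 5), rep("abnormal", 5)),
                     labels = rep(c(1, 0), each = 5))
  expect_equal(b3$spec_lower_bound, 1)
  expect_error(node1_bounds(rep("normal", 4), labels = rep(1, 4)), "both")
})

test_that("a self-consistent cohort gives perfect operating points at s0", {
  cohort <- oracle_fixed_tree_cohort(n = 78, s0 = 80)
  sweep <- mc_threshold_sweep(cohort, n_sample = 100, reps = 200, seed = 5)
  at <- sweep_at(sweep, 80)
  expect_equal(at$sens_mean, 1)
  expect_equal(at$spec_mean, 1)
  expect_equal(at$sens_se, 0)
  expect_equal(at$spec_se, 0)
  expect_true(sweep$bounds_respected)
})

test_that("sweeps are deterministic and monotone in the cutoff", {
  cohort <- oracle_fixed_tree_cohort(n = 78, s0 = 80)
  # noisy truth: flip some labels so the curves are non-trivial
  set.seed(61)
  flip <- sample(78, 15)
  cohort$labels[flip] <- 1L - cohort$labels[flip]
  s1 <- mc_threshold_sweep(cohort, n_sample = 100, reps = 300, seed = 13)
  s2 <- mc_threshold_sweep(cohort, n_sample = 100, reps = 300, seed = 13)
  expect_identical(s1, s2)
  expect_true(s1$bounds_respected)
  expect_true(all(diff(s1$table$sens_mean) <= 1e-12))
  expect_true(all(diff(s1$table$spec_mean) >= -1e-12))
  expect_true(all(s1$table$sens_mean >= 0 & s1$table$sens_mean <= 1))

  # grid spans the observed baselines in 0.5 steps
  expect_equal(s1$table$cutoff[1], floor(min(cohort$data$baseline_bfm)))
  expect_equal(diff(s1$table$cutoff[1:2]), 0.5)
})

test_that("sweep means converge to full-cohort metrics within 3 SE", {
  cohort <- oracle_fixed_tree_cohort(n = 78, s0 = 80)
  set.seed(62)
  flip <- sample(78, 20)
  cohort$labels[flip] <- 1L - cohort$labels[flip]
  sweep <- mc_threshold_sweep(cohort, n_sample = 100, reps = 1000, seed = 19)
  y <- cohort$labels
  for (cut in c(60, 80, 100)) {
    preds <- fixed_tree_predict(cohort$data$cmct, cohort$data$baseline_bfm, cut)
    m <- compute_metrics(confusion(preds, y))
    at <- sweep_at(sweep, cut)
    expect_lt(abs(at$sens_mean - m$sensitivity), 3 * max(at$sens_se, 1e-3))
    expect_lt(abs(at$spec_mean - m$specificity), 3 * max(at$spec_se, 1e-3))
  }
})

test_that("extreme cutoffs reach the closed-form limits", {
  cohort <- oracle_fixed_tree_cohort(n = 78, s0 = 80)
  set.seed(63)
  flip <- sample(78, 20)
  cohort$labels[flip] <- 1L - cohort$labels[flip]
  lo <- min(cohort$data$baseline_bfm) - 1
  hi <- max(cohort$data$baseline_bfm) + 1
  sweep <- mc_threshold_sweep(cohort, cutoffs = c(lo, hi), n_sample = 100,
                              reps = 500, seed = 23)
  # cutoff below every baseline: all CMCT-normal predicted favorable, so
  # specificity equals the abnormal-CMCT fraction of negatives (up to MC error)
  neg_abn <- mean(cohort$data$cmct[cohort$labels == 0] == "abnormal")
  at_lo <- sweep$table[1, ]
  expect_lt(abs(at_lo$spec_mean - neg_abn), 3 * max(at_lo$spec_se, 1e-3))
  # cutoff above every baseline: nobody predicted favorable
  at_hi <- sweep$table[2, ]
  expect_equal(at_hi$sens_mean, 0)
  expect_equal(at_hi$spec_mean, 1)
})

test_that("ROC points live inside the node-1 rectangle and order by cutoff", {
  cohort <- oracle_fixed_tree_cohort(n = 78, s0 = 80)
  set.seed(64)
  flip <- sample(78, 20)
  cohort$labels[flip] <- 1L - cohort$labels[flip]
  sweep <- mc_threshold_sweep(cohort, n_sample = 100, reps = 400, seed = 29)
  roc <- roc_points(sweep)
  expect_equal(roc$cutoff, sweep$table$cutoff)
  expect_true(all(diff(roc$fpr) <= 1e-12)) # FPR non-increasing with cutoff
  slack <- 3 * pmax(sweep$table$sens_se, 1e-3)
  expect_true(all(roc$tpr <= sweep$sens_upper_bound + slack))
  expect_true(all(roc$fpr <= 1 - sweep$spec_lower_bound + 3 * pmax(sweep$table$spec_se, 1e-3)))
})
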