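test_that("AUC follows the pair-counting definition", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.2, 0.1),
                                c(TRUE, TRUE, FALSE, FALSE)), 1)
  # 3 concordant of 4 pairs
  expect_equal(auc_mann_whitney(c(0.9, 0.7, 0.8, 0.6),
                                c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc_mann_whitney(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc_mann_whitney(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC matches the exhaustive pair oracle on small random data", {
  set.seed(1)
  for (i in 1:300) {
    n <- sample(4:12, 1)
    n1 <- sample(seq_len(n - 1), 1)
    pos <- sample(c(rep(TRUE, n1), rep(FALSE, n - n1)))
    scores <- sample(round(runif(n), 2))  # rounded to force ties
    expect_equal(auc_mann_whitney(scores, pos), oracle_auc_pairs(scores, pos))
  }
})

test_that("AUC and DeLong interval agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(2)
  for (i in 1:20) {
    pos <- c(rep(TRUE, 25), rep(FALSE, 30))
    scores <- rnorm(55, mean = ifelse(pos, 1, 0))
    roc <- pROC::roc(response = pos, predictor = scores, quiet = TRUE,
                     direction = "<", levels = c(FALSE, TRUE))
    expect_equal(auc_mann_whitney(scores, pos), as.numeric(pROC::auc(roc)),
                 tolerance = 1e-12)
    ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
    ours <- delong_ci(scores, pos)
    expect_equal(c(ours$lower, ours$upper), ci[c(1, 3)], tolerance = 1e-9)
  }
})

test_that("DeLong interval degenerates and stays bounded correctly", {
  pos <- c(rep(TRUE, 5), rep(FALSE, 5))
  perfect <- delong_ci(c(2:6, -5:-1), pos)
  expect_equal(perfect$se, 0)
  expect_equal(c(perfect$lower, perfect$upper), c(1, 1))
  set.seed(3)
  for (i in 1:1000) {
    n1 <- sample(2:6, 1); n0 <- sample(2:6, 1)
    ci <- delong_ci(rnorm(n1 + n0), rep(c(TRUE, FALSE), c(n1, n0)))
    expect_gte(ci$lower, 0); expect_lte(ci$upper, 1)
    expect_gte(ci$auc, ci$lower); expect_lte(ci$auc, ci$upper)
  }
})

test_that("Youden cutoffs use midpoints with specificity tie-breaks", {
  # low marker values indicate the positive class
  res <- youden_cutoff(c(0.02, 0.05, 0.30, 0.50),
                       c(TRUE, TRUE, FALSE, FALSE), direction = "<")
  expect_equal(res$cutoff, 0.175)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$youden, 1)
  # all tied: J = 0 at the single observed value
  tied <- youden_cutoff(rep(2, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(tied$youden, 0)
  expect_equal(tied$cutoff, 2)
})

test_that("flipping orientation mirrors AUC", {
  set.seed(4)
  for (i in 1:50) {
    pos <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(pos)) < 2) next
    s <- rnorm(30)
    expect_equal(auc_mann_whitney(s, pos, direction = "<"),
                 1 - auc_mann_whitney(s, pos, direction = ">"),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap intervals collapse on degenerate data", {
  pos <- rep(c(TRUE, FALSE), c(10, 10))
  bt_tied <- bootstrap_auc(rep(1, 20), pos, B = 100, seed = 1)
  expect_equal(bt_tied$interval, c(0.5, 0.5))
  bt_perf <- bootstrap_auc(c(rep(2, 10), rep(1, 10)), pos, B = 100, seed = 1)
  expect_equal(bt_perf$interval, c(1, 1))
})

test_that("permutation p has the add-one floor and matches enumeration", {
  # perfect separation at n = 32 + 50: zero exceedances at B = 5000
  pos <- rep(c(TRUE, FALSE), c(32, 50))
  s <- c(rnorm(32, 10), rnorm(50, 0))
  pt <- permutation_test(s, pos, B = 5000, seed = 5)
  expect_equal(pt$exceedances, 0L)
  expect_equal(pt$p, 1 / 5001)
  expect_gt(pt$p, 0)
  # tiny case: compare against exhaustive enumeration of all 10 arrangements
  s2 <- c(3, 5, 1, 2, 4)
  pos2 <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  obs <- auc_mann_whitney(s2, pos2)
  combos <- combn(5, 3)
  exact <- mean(apply(combos, 2, function(ix) {
    auc_mann_whitney(s2, seq_len(5) %in% ix) >= obs - 1e-12
  }))
  pt2 <- permutation_test(s2, pos2, B = 4000, seed = 6)
  expect_lt(abs(pt2$p - exact), 0.05)
})

test_that("repeated holdout and k-fold suites behave on perfect markers", {
  pos <- rep(c(TRUE, FALSE), c(20, 30))
  s <- c(rnorm(20, 10), rnorm(30, 0))
  ho <- repeated_holdout_auc(s, pos, repeats = 50, seed = 7)
  expect_equal(ho$range, c(1, 1))
  kf <- repeated_kfold_auc(s, pos, k = 5, repetitions = 20, seed = 7)
  expect_equal(kf$interval, c(1, 1))
  # determinism of the full suite
  m1 <- marker_inference(s, pos, B_boot = 50, B_perm = 50,
                         holdout_repeats = 20, kfold_repetitions = 10,
                         seed = 9)
  m2 <- marker_inference(s, pos, B_boot = 50, B_perm = 50,
                         holdout_repeats = 20, kfold_repetitions = 10,
                         seed = 9)
  expect_equal(m1[names(m1) != "seed"], m2[names(m2) != "seed"])
})

test_that("a null marker centres the holdout range on chance", {
  set.seed(10)
  s <- rnorm(82)
  pos <- rep(c(TRUE, FALSE), c(32, 50))
  ho <- repeated_holdout_auc(s, pos, repeats = 200, seed = 11)
  expect_lt(ho$range[1], 0.5)
  expect_gt(ho$range[2], 0.5)
})

test_that("fold-mean averaging narrows the repeated k-fold interval", {
  coh <- generate_cohort(planted_two_group_cohort(d = 2.56), seed = 12)
  kf <- repeated_kfold_auc(coh$DCA, coh$group, positive = "NMOSD_AQP4neg",
                           direction = "<", k = 5, repetitions = 100,
                           seed = 13)
  expect_lt(diff(kf$interval), 0.05)
})
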