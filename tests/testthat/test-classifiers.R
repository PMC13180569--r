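# well-separated two-feature toy problem
separable_data <- function(n = 60, gap = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  x <- cbind(f1 = rnorm(n) + gap * y, f2 = rnorm(n))
  list(x = x, y = y)
}

test_that("metric identities reproduce the diagnostic-table arithmetic", {
  # 32 positives at sensitivity 1.000, 50 negatives at specificity 0.900
  m <- classification_metrics(tp = 32, fp = 5, tn = 45, fn = 0)
  expect_equal(m$accuracy, 77 / 82, tolerance = 5e-4)   # 0.939
  expect_equal(m$f1, 64 / 69, tolerance = 5e-4)         # 0.928
  expect_equal(m$balanced_accuracy, 0.950)
  expect_equal(m$youden, 0.900)
  # sensitivity 0.9, specificity 0.826
  m2 <- classification_metrics(tp = 9, fp = 4, tn = 19, fn = 1)
  expect_equal(m2$sensitivity, 0.9)
  expect_equal(m2$specificity, 0.826, tolerance = 5e-4)
  expect_equal(m2$balanced_accuracy, (0.9 + m2$specificity) / 2)
  expect_equal(m2$balanced_accuracy, 0.863, tolerance = 5e-4)
  expect_equal(m2$youden, 0.726, tolerance = 5e-4)
  # perfect classifier
  m3 <- classification_metrics(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_true(all(unlist(m3[c("accuracy", "sensitivity", "specificity",
                              "balanced_accuracy", "f1", "youden")]) == 1))
})

test_that("metric identities hold against a brute-force confusion oracle", {
  for (tp in 0:5) for (fp in 0:5) for (tn in 0:5) for (fn in 0:5) {
    if (tp + fn == 0 || tn + fp == 0 || tp + fp + tn + fn == 0) next
    truth <- rep(c(TRUE, TRUE, FALSE, FALSE), c(tp, fn, tn, fp))
    called <- rep(c(TRUE, FALSE, FALSE, TRUE), c(tp, fn, tn, fp))
    m <- classification_metrics(tp, fp, tn, fn)
    expect_equal(m$accuracy, mean(truth == called))
    expect_equal(m$sensitivity, mean(called[truth]))
    expect_equal(m$specificity, mean(!called[!truth]))
    expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    expect_equal(m$youden, m$sensitivity + m$specificity - 1)
    if (2 * tp + fp + fn > 0) {
      precision <- if (tp + fp == 0) NaN else tp / (tp + fp)
      if (!is.nan(precision) && precision + m$sensitivity > 0) {
        expect_equal(m$f1, 2 * precision * m$sensitivity /
                       (precision + m$sensitivity))
      }
    }
  }
})

test_that("best-threshold metrics reproduce the single-marker panel", {
  # 32 positives clustered low FP region: threshold lands between clusters
  probs <- c(rep(0.9, 32), rep(0.1, 45), rep(0.95, 5))
  labels <- rep(c(TRUE, FALSE), c(32, 50))
  ms <- metrics_at_best_threshold(probs, labels)
  expect_equal(ms$sensitivity, 1.000)
  expect_equal(ms$specificity, 0.900)
  expect_equal(ms$accuracy, 77 / 82)
  expect_equal(ms$f1, 64 / 69)
  expect_equal(ms$balanced_accuracy, 0.950)
  expect_equal(ms$youden, 0.900)
  expect_error(metrics_at_best_threshold(probs[1:32], labels[1:32]),
               "one class")
})

test_that("every classifier kind separates an easy problem", {
  dat <- separable_data()
  for (kind in c("logistic", "random_forest", "svm_linear", "gbt")) {
    mod <- train_model(kind, dat$x, dat$y, seed = 2)
    p <- predict_prob(mod, dat$x)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(auc_mann_whitney(p, dat$y == 1), 1, tolerance = 1e-9,
                 label = kind)
  }
})

test_that("grid search is deterministic given the seed", {
  dat <- separable_data(seed = 3)
  m1 <- train_model("gbt", dat$x, dat$y, seed = 5)
  m2 <- train_model("gbt", dat$x, dat$y, seed = 5)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  s1 <- train_model("svm_linear", dat$x, dat$y, seed = 7)
  s2 <- train_model("svm_linear", dat$x, dat$y, seed = 7)
  expect_identical(s1$hyperparameters, s2$hyperparameters)
})

test_that("label-permuted data yields chance-level cross-validated AUC", {
  cv_means <- vapply(1:5, function(r) {
    set.seed(10 + r)
    x <- matrix(rnorm(120 * 6), 120, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- sample(rep(c(1, 0), each = 60))
    mod <- train_model("logistic", x, y, seed = 13)
    vs <- three_level_validation(list(logistic = mod), x, y,
                                 x[1:40, ], y[1:40], reps = 2, k = 5,
                                 boot_B = 20, seed = 14 + r)
    # coefficient of variation is SD over mean by definition
    expect_equal(vs$models$logistic$cv_coefficient,
                 vs$models$logistic$cv_sd / vs$models$logistic$cv_mean)
    vs$models$logistic$cv_mean
  }, numeric(1))
  expect_lt(abs(mean(cv_means) - 0.5), 0.05)
})

test_that("three-level validation is exact for a deterministic perfect model", {
  dat <- separable_data(n = 80, gap = 20, seed = 17)
  mod <- train_model("logistic", dat$x, dat$y, seed = 19)
  vs <- three_level_validation(list(m = mod), dat$x, dat$y, dat$x, dat$y,
                               reps = 2, k = 4, boot_B = 100, seed = 21)
  expect_equal(vs$models$m$cv_mean, 1)
  expect_equal(vs$models$m$cv_sd, 0)
  expect_equal(vs$models$m$boot_interval, c(1, 1))
  expect_equal(vs$models$m$holdout_best$auc, 1)
  expect_error(three_level_validation(list(m = mod), dat$x, dat$y,
                                      dat$x[1:5, ], rep(1, 5)),
               "class")
})

test_that("logistic summaries expose Wald arithmetic and catch separation", {
  set.seed(23)
  n <- 400
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  y <- rbinom(n, 1, plogis(0.7 * x[, "f1"]))
  mod <- train_model("logistic", x, y, seed = 25)
  tab <- summarize_logistic(mod)
  expect_false(attr(tab, "separation"))
  expect_equal(tab$wald_z, tab$coefficient / tab$std_error)
  expect_equal(tab$odds_ratio, exp(tab$coefficient))
  expect_equal(tab$or_lower, exp(tab$coefficient - 1.96 * tab$std_error))
  expect_equal(tab$or_upper, exp(tab$coefficient + 1.96 * tab$std_error))
  # consistency: large-sample estimate within 3 SE of the truth
  b1 <- tab[tab$term == "f1", ]
  expect_lt(abs(b1$coefficient - 0.7), 3 * b1$std_error)
  # complete separation is flagged and intervals suppressed
  xs <- cbind(f1 = c(rnorm(20, -8), rnorm(20, 8)))
  ys <- rep(c(0, 1), each = 20)
  sep_mod <- train_model("logistic", xs, ys, seed = 27)
  sep_tab <- summarize_logistic(sep_mod)
  expect_true(attr(sep_tab, "separation"))
  expect_true(all(is.na(sep_tab$or_lower)))
})
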