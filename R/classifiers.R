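#' Default hyperparameter grids for the benchmark classifiers
#'
#' Frozen grids searched by inner cross-validation: none for logistic
#' regression; trees in \{200, 500\} crossed with maximum tree size in
#' \{small, medium, unlimited\} for random forest; cost in
#' \{0.01, 0.1, 1, 10\} for the linear SVM; learning rate \{0.05, 0.1\},
#' rounds \{100, 300\} and depth \{2, 3\} for gradient-boosted trees.
#'
#' @param kind Model kind.
#' @return Data frame, one row per grid point (possibly a single empty row).
#' @export
default_grid <- function(kind) {
  switch(kind,
    logistic = data.frame(row.names = 1),
    lasso_logistic = data.frame(row.names = 1),
    random_forest = expand.grid(ntree = c(200, 500), maxnodes = c(8, 32, NA)),
    svm_linear = data.frame(cost = c(0.01, 0.1, 1, 10)),
    gbt = expand.grid(eta = c(0.05, 0.1), nrounds = c(100, 300),
                      max_depth = c(2, 3)),
    stop("unknown model kind: ", kind))
}

# fit one model of the given kind with fixed hyperparameters
fit_one <- function(kind, x, y01, params, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (kind %in% c("logistic", "lasso_logistic")) {
    df <- data.frame(.y = y01, x, check.names = FALSE)
    suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  } else if (kind == "random_forest") {
    maxnodes <- if (is.na(params$maxnodes)) NULL else params$maxnodes
    randomForest::randomForest(x = x, y = factor(y01, levels = c(0, 1)),
                               ntree = params$ntree, maxnodes = maxnodes)
  } else if (kind == "svm_linear") {
    e1071::svm(x = x, y = factor(y01, levels = c(0, 1)), kernel = "linear",
               cost = params$cost, probability = TRUE, scale = FALSE)
  } else if (kind == "gbt") {
    dm <- xgboost::xgb.DMatrix(x, label = y01)
    xgboost::xgb.train(params = list(objective = "binary:logistic",
                                     eta = params$eta,
                                     max_depth = params$max_depth,
                                     nthread = 1),
                       data = dm, nrounds = params$nrounds, verbose = 0)
  } else stop("unknown model kind: ", kind)
}

predict_one <- function(kind, fit, newx) {
  if (kind %in% c("logistic", "lasso_logistic")) {
    df <- as.data.frame(newx)
    unname(stats::predict(fit, newdata = df, type = "response"))
  } else if (kind == "random_forest") {
    unname(stats::predict(fit, newdata = newx, type = "prob")[, "1"])
  } else if (kind == "svm_linear") {
    pr <- stats::predict(fit, newdata = newx, probability = TRUE)
    unname(attr(pr, "probabilities")[, "1"])
  } else if (kind == "gbt") {
    unname(stats::predict(fit, newdata = xgboost::xgb.DMatrix(newx)))
  } else stop("unknown model kind: ", kind)
}

#' Train one benchmark classifier with inner-CV hyperparameter selection
#'
#' Hyperparameters are chosen by mean AUC over stratified inner folds on the
#' (pre-standardized) training features restricted to the given feature set,
#' then the model is refit on the full training data. SVM decision values are
#' mapped to probabilities by the Platt-type sigmoid calibration fit during
#' training. For `kind = "lasso_logistic"` the feature set is first obtained
#' by [single_lasso_reference()] and an unpenalized logistic model is fit on
#' it.
#'
#' @param kind One of `"logistic"`, `"random_forest"`, `"svm_linear"`,
#'   `"gbt"`, `"lasso_logistic"`.
#' @param x Pre-standardized training feature matrix.
#' @param y Binary labels.
#' @param positive Positive class label.
#' @param features Feature subset to use (default all columns).
#' @param k Inner folds for the grid search (default 5).
#' @param grid Hyperparameter grid (default [default_grid()]).
#' @param seed Integer seed.
#' @return Object of class `ba_model`.
#' @export
train_model <- function(kind, x, y, positive = NULL,
                        features = colnames(x), k = 5,
                        grid = default_grid(kind), seed = NULL) {
  x <- as.matrix(x)
  y01 <- binary_response(y, positive)
  if (kind == "lasso_logistic") {
    features <- as.character(single_lasso_reference(x, y01, k = 10, seed = seed))
    if (length(features) == 0) features <- colnames(x)
  }
  xs <- x[, features, drop = FALSE]
  chosen <- grid[1, , drop = FALSE]
  if (nrow(grid) > 1) {
    fold <- as.integer(assign_folds(y01, k = k,
                                    seed = if (is.null(seed)) NULL else seed + 17L))
    cv_auc <- vapply(seq_len(nrow(grid)), function(gi) {
      mean(vapply(seq_len(k), function(f) {
        tr <- fold != f
        fit <- fit_one(kind, xs[tr, , drop = FALSE], y01[tr],
                       grid[gi, , drop = FALSE],
                       seed = if (is.null(seed)) NULL else seed + 100L * gi + f)
        auc_mann_whitney(predict_one(kind, fit, xs[!tr, , drop = FALSE]),
                         y01[!tr] == 1)
      }, numeric(1)))
    }, numeric(1))
    chosen <- grid[which.max(cv_auc), , drop = FALSE]
  }
  fit <- fit_one(kind, xs, y01, chosen,
                 seed = if (is.null(seed)) NULL else seed + 1L)
  structure(list(kind = kind, fit = fit, features = features,
                 hyperparameters = chosen, seed = seed),
            class = "ba_model")
}

#' Predicted positive-class probabilities from a benchmark model
#'
#' @param model A `ba_model`.
#' @param newx Feature matrix (pre-standardized, same convention as training).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_prob <- function(model, newx) {
  newx <- as.matrix(newx)[, model$features, drop = FALSE]
  p <- predict_one(model$kind, model$fit, newx)
  pmin(pmax(p, 0), 1)
}

#' @export
print.ba_model <- function(x, ...) {
  cat("Benchmark classifier:", x$kind, "on", length(x$features), "feature(s)\n")
  if (ncol(x$hyperparameters) > 0) {
    cat("  hyperparameters:",
        paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classification metric panel from a confusion matrix
#'
#' The metric identities used throughout: accuracy, sensitivity, specificity,
#' balanced accuracy = (sensitivity + specificity) / 2, Youden
#' J = sensitivity + specificity - 1, and F1 = 2TP / (2TP + FP + FN) with the
#' designated positive class.
#'
#' @param tp,fp,tn,fn Confusion-matrix cell counts.
#' @return Named list of metrics.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(accuracy = (tp + tn) / (tp + fp + tn + fn),
       sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       f1 = 2 * tp / (2 * tp + fp + fn),
       youden = sens + spec - 1,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Metric panel at a fixed or Youden-optimal probability threshold
#'
#' When `threshold` is `NULL` the threshold maximizing Youden's J over
#' midpoints of consecutive distinct scores is used (ties broken toward
#' higher specificity); otherwise subjects with probability at or above the
#' given threshold are called positive. The AUC and its DeLong interval are
#' reported alongside.
#'
#' @param probabilities Predicted positive-class probabilities.
#' @param labels Class labels.
#' @param positive Positive class label.
#' @param threshold Fixed threshold, or `NULL` to optimize Youden's J.
#' @return Object of class `metric_set`: the [classification_metrics()] panel
#'   plus `auc`, `auc_ci`, `threshold`.
#' @export
metrics_at_best_threshold <- function(probabilities, labels, positive = NULL,
                                      threshold = NULL) {
  pos <- pos_indicator(labels, positive)
  if (length(unique(pos)) < 2) stop("AUC undefined: only one class present")
  dl <- delong_ci(probabilities, pos)
  if (is.null(threshold)) {
    yc <- youden_cutoff(probabilities, pos)
    threshold <- yc$cutoff
  }
  call_pos <- probabilities >= threshold
  m <- classification_metrics(tp = sum(call_pos & pos),
                              fp = sum(call_pos & !pos),
                              tn = sum(!call_pos & !pos),
                              fn = sum(!call_pos & pos))
  structure(c(list(auc = dl$auc, auc_ci = c(dl$lower, dl$upper),
                   threshold = threshold), m),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(paste0("AUC %.3f (%.3f-%.3f)  acc %.3f  bal.acc %.3f  sens %.3f",
                     "  spec %.3f  F1 %.3f  J %.3f  thr %.3g\n"),
              x$auc, x$auc_ci[1], x$auc_ci[2], x$accuracy,
              x$balanced_accuracy, x$sensitivity, x$specificity, x$f1,
              x$youden, x$threshold))
  invisible(x)
}

#' Three-level validation of a set of trained classifiers
#'
#' (1) Stability: repeated stratified k-fold cross-validation on the training
#' set (default 10 repetitions of 5 folds, so 50 fold AUCs per model),
#' retraining each model with its already-selected hyperparameters; reported
#' as mean, SD and coefficient of variation. (2) Robustness: stratified
#' bootstrap of the independent test set (default 1000 resamples) giving a
#' percentile AUC interval. (3) Generalizability: the hold-out metric panel,
#' reported both at the Youden-optimal threshold and at 0.5.
#'
#' @param models Named list of trained `ba_model`s (sharing the training data).
#' @param x_train,y_train Training features (pre-standardized) and labels.
#' @param x_test,y_test Hold-out features and labels.
#' @param positive Positive class label.
#' @param reps,k Repeated-CV shape (defaults 10 and 5).
#' @param boot_B Test-set bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Object of class `validation_summary`: per-model summaries, the
#'   models-by-folds CV AUC matrix (`cv_auc_matrix`) and the models-by-B
#'   bootstrap AUC matrix (`boot_auc_matrix`) for downstream comparison.
#' @export
three_level_validation <- function(models, x_train, y_train, x_test, y_test,
                                   positive = NULL, reps = 10, k = 5,
                                   boot_B = 1000, seed = NULL) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  ytr <- binary_response(y_train, positive)
  yte <- binary_response(y_test, positive)
  if (length(unique(yte)) < 2) stop("test set must contain both classes")
  n_fold_aucs <- reps * k
  cv_mat <- matrix(NA_real_, nrow = length(models), ncol = n_fold_aucs,
                   dimnames = list(names(models), NULL))
  for (r in seq_len(reps)) {
    fold <- as.integer(assign_folds(ytr, k = k,
                                    seed = if (is.null(seed)) NULL else seed + r))
    for (f in seq_len(k)) {
      tr <- fold != f
      for (m in names(models)) {
        mod <- models[[m]]
        fit <- fit_one(mod$kind, x_train[tr, mod$features, drop = FALSE],
                       ytr[tr], mod$hyperparameters,
                       seed = if (is.null(seed)) NULL else seed + 1000L * r + f)
        p <- predict_one(mod$kind, fit,
                         x_train[!tr, mod$features, drop = FALSE])
        cv_mat[m, (r - 1) * k + f] <- auc_mann_whitney(p, ytr[!tr] == 1)
      }
    }
  }
  test_probs <- lapply(models, predict_prob, newx = x_test)
  if (!is.null(seed)) set.seed(seed + 99991L)
  ip <- which(yte == 1); ineg <- which(yte == 0)
  boot_mat <- matrix(NA_real_, nrow = length(models), ncol = boot_B,
                     dimnames = list(names(models), NULL))
  for (b in seq_len(boot_B)) {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    for (m in names(models)) {
      boot_mat[m, b] <- auc_mann_whitney(test_probs[[m]][idx], yte[idx] == 1)
    }
  }
  per_model <- lapply(names(models), function(m) {
    cv <- cv_mat[m, ]
    list(kind = models[[m]]$kind,
         cv_mean = mean(cv), cv_sd = stats::sd(cv),
         cv_coefficient = stats::sd(cv) / mean(cv),
         boot_interval = unname(stats::quantile(boot_mat[m, ], c(0.025, 0.975))),
         holdout_best = metrics_at_best_threshold(test_probs[[m]], yte == 1),
         holdout_05 = metrics_at_best_threshold(test_probs[[m]], yte == 1,
                                                threshold = 0.5))
  })
  names(per_model) <- names(models)
  structure(list(models = per_model, cv_auc_matrix = cv_mat,
                 boot_auc_matrix = boot_mat, reps = reps, k = k,
                 boot_B = boot_B, seed = seed),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("Three-level validation (%d x %d-fold CV, %d test bootstraps)\n",
              x$reps, x$k, x$boot_B))
  for (m in names(x$models)) {
    s <- x$models[[m]]
    cat(sprintf("%-18s CV AUC %.3f +/- %.3f (CV %.3f)  boot %.3f-%.3f  holdout AUC %.3f\n",
                m, s$cv_mean, s$cv_sd, s$cv_coefficient,
                s$boot_interval[1], s$boot_interval[2], s$holdout_best$auc))
  }
  invisible(x)
}

#' Coefficient summary of a fitted logistic model
#'
#' Per-feature coefficient B (log-odds change per unit of the standardized
#' variable), standard error, Wald z = B/SE, two-sided p, odds ratio exp(B)
#' and 95% CI exp(B +/- 1.96 SE). If the fit did not converge or shows signs
#' of separation (huge standard errors) the summary is flagged and the
#' intervals suppressed.
#'
#' @param model A `ba_model` of logistic kind (or a `glm` fit).
#' @return Data frame with one row per term; attribute `separation` flags
#'   unreliable fits.
#' @export
summarize_logistic <- function(model) {
  fit <- if (inherits(model, "ba_model")) model$fit else model
  if (!inherits(fit, "glm")) stop("summarize_logistic needs a logistic model")
  cf <- summary(fit)$coefficients
  separation <- !fit$converged || any(cf[, "Std. Error"] > 50)
  out <- data.frame(
    term = rownames(cf),
    coefficient = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    wald_z = cf[, "Estimate"] / cf[, "Std. Error"],
    p_value = 2 * stats::pnorm(-abs(cf[, "Estimate"] / cf[, "Std. Error"])),
    odds_ratio = exp(cf[, "Estimate"]),
    or_lower = exp(cf[, "Estimate"] - 1.96 * cf[, "Std. Error"]),
    or_upper = exp(cf[, "Estimate"] + 1.96 * cf[, "Std. Error"]),
    row.names = NULL
  )
  if (separation) out$or_lower <- out$or_upper <- NA_real_
  attr(out, "separation") <- separation
  out
}
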