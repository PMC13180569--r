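# binary response as 0/1 with a designated positive class
binary_response <- function(y, positive = NULL) {
  if (is.logical(y)) return(as.integer(y))
  vals <- unique(as.character(y))
  if (length(vals) != 2) stop("labels must be binary (got ",
                              length(vals), " classes)")
  if (is.null(positive)) positive <- sort(vals)[2]
  as.integer(as.character(y) == as.character(positive))
}

#' The one-standard-error rule on a cross-validation error curve
#'
#' Given a descending penalty grid with mean cross-validated error and its
#' standard error per penalty, returns the penalty minimizing the mean error
#' (`lambda_min`) and the largest penalty whose mean error is within one
#' standard error of that minimum (`lambda_1se`) — the parsimony-favoring
#' choice.
#'
#' @param lambda Penalty grid.
#' @param cvm Mean cross-validated error per penalty.
#' @param cvsd Standard error of the cross-validated error per penalty.
#' @return List with `lambda_min` and `lambda_1se`.
#' @export
lambda_1se_rule <- function(lambda, cvm, cvsd) {
  stopifnot(length(lambda) == length(cvm), length(cvm) == length(cvsd))
  i_min <- which.min(cvm)
  threshold <- cvm[i_min] + cvsd[i_min]
  list(lambda_min = lambda[i_min],
       lambda_1se = max(lambda[cvm <= threshold + 1e-12]))
}

#' Cross-validated LASSO logistic regression
#'
#' L1-penalized logistic regression over a glmnet-style descending penalty
#' grid (100 values down to 1e-3 of the data-derived maximum), scored by
#' binomial deviance over stratified folds. Features are expected to be
#' pre-standardized; no internal rescaling is applied and the intercept is
#' unpenalized. The 1-SE penalty is chosen by [lambda_1se_rule()].
#'
#' @param x Numeric feature matrix (pre-standardized).
#' @param y Binary labels.
#' @param positive Positive class label.
#' @param k Number of stratified folds (default 5).
#' @param foldid Optional explicit fold ids (overrides `k`/`seed`).
#' @param seed Integer seed for the fold assignment.
#' @param nlambda,lambda_min_ratio Penalty-grid shape.
#' @return Object of class `lasso_cv`: `lambda`, `cvm`, `cvsd`, `lambda_min`,
#'   `lambda_1se`, `active` (active set at `lambda_1se`), `beta_1se`, `fit`.
#' @export
lasso_cv <- function(x, y, positive = NULL, k = 5, foldid = NULL, seed = NULL,
                     nlambda = 100, lambda_min_ratio = 1e-3) {
  x <- as.matrix(x)
  yb <- binary_response(y, positive)
  if (is.null(foldid)) foldid <- as.integer(assign_folds(yb, k = k, seed = seed))
  cv <- glmnet::cv.glmnet(x, yb, family = "binomial", foldid = foldid,
                          type.measure = "deviance", standardize = FALSE,
                          nlambda = nlambda, lambda.min.ratio = lambda_min_ratio)
  rule <- lambda_1se_rule(cv$lambda, cv$cvm, cv$cvsd)
  beta <- as.matrix(stats::coef(cv$glmnet.fit, s = rule$lambda_1se))[-1, 1]
  structure(list(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                 lambda_min = rule$lambda_min, lambda_1se = rule$lambda_1se,
                 active = names(beta)[beta != 0], beta_1se = beta,
                 glmnet_lambda_1se = cv$lambda.1se, fit = cv$glmnet.fit),
            class = "lasso_cv")
}

#' Active set of a cross-validated LASSO fit at a given penalty
#'
#' @param object A `lasso_cv`.
#' @param lambda Penalty (default the fit's `lambda_1se`).
#' @return Character vector of features with nonzero coefficients.
#' @export
active_set <- function(object, lambda = object$lambda_1se) {
  beta <- as.matrix(stats::coef(object$fit, s = lambda))[-1, 1]
  names(beta)[beta != 0]
}

#' Stability selection via nested cross-validation
#'
#' Outer stratified K-fold cross-validation; within each outer training
#' portion an inner stratified cross-validated LASSO picks its active set at
#' the 1-SE penalty. A feature's stability score is the fraction of outer
#' folds in which it was active (a multiple of 1/K); features at or above the
#' threshold form the retained set.
#'
#' @param x Pre-standardized feature matrix.
#' @param y Binary labels.
#' @param positive Positive class label.
#' @param outer_k,inner_k Outer and inner fold counts (defaults 5 and 5).
#' @param threshold Retention threshold on the stability score (default 0.5).
#' @param seed Integer seed.
#' @return Object of class `stability_result`: named `frequency` vector,
#'   `retained` features, `threshold`, `outer_k`, per-fold active sets and
#'   the mean sign of each feature's coefficient across the folds where it
#'   was active.
#' @export
nested_stability_selection <- function(x, y, positive = NULL, outer_k = 5,
                                       inner_k = 5, threshold = 0.5,
                                       seed = NULL) {
  x <- as.matrix(x)
  yb <- binary_response(y, positive)
  if (min(table(yb)) < outer_k) stop("need at least outer_k subjects per class")
  outer <- assign_folds(yb, k = outer_k, seed = seed)
  sets <- vector("list", outer_k)
  signs <- matrix(0, nrow = outer_k, ncol = ncol(x),
                  dimnames = list(NULL, colnames(x)))
  for (f in seq_len(outer_k)) {
    tr <- outer != f
    cvfit <- lasso_cv(x[tr, , drop = FALSE], yb[tr], k = inner_k,
                      seed = if (is.null(seed)) NULL else seed + f)
    sets[[f]] <- cvfit$active
    signs[f, ] <- sign(cvfit$beta_1se)
  }
  freq <- colMeans(do.call(rbind, lapply(sets, function(s) colnames(x) %in% s)))
  names(freq) <- colnames(x)
  mean_sign <- vapply(colnames(x), function(j) {
    active_signs <- signs[signs[, j] != 0, j]
    if (length(active_signs) == 0) 0 else mean(active_signs)
  }, numeric(1))
  structure(list(frequency = freq,
                 retained = names(freq)[freq >= threshold - 1e-12],
                 threshold = threshold, outer_k = outer_k,
                 fold_sets = sets, mean_sign = mean_sign, seed = seed),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Stability selection over", x$outer_k, "outer folds (threshold",
      paste0(100 * x$threshold, "%):"), length(x$retained),
      "feature(s) retained\n")
  if (length(x$retained) > 0) {
    sel <- sort(x$frequency[x$retained], decreasing = TRUE)
    for (nm in names(sel)) {
      cat(sprintf("  %-32s %3.0f%%\n", nm, 100 * sel[[nm]]))
    }
  }
  invisible(x)
}

#' Single-run LASSO reference feature set
#'
#' One cross-validated LASSO on the entire training-validation set (10 folds
#' by default) returning the active set at the 1-SE penalty — the
#' conventional single-shot alternative that the stability-selected set is
#' compared against.
#'
#' @inheritParams nested_stability_selection
#' @param k Number of folds (default 10).
#' @return Character vector of selected features (attribute `fit` carries the
#'   underlying `lasso_cv`).
#' @export
single_lasso_reference <- function(x, y, positive = NULL, k = 10, seed = NULL) {
  fit <- lasso_cv(x, y, positive = positive, k = k, seed = seed)
  structure(fit$active, fit = fit)
}

#' Write a stability result as a tidy CSV
#'
#' Columns: feature, stability frequency, retained flag, mean coefficient
#' sign across the folds where the feature was active.
#'
#' @param x A `stability_result`.
#' @param path File path.
#' @export
write_stability_csv <- function(x, path) {
  utils::write.csv(data.frame(
    feature = names(x$frequency),
    frequency = unname(x$frequency),
    retained = names(x$frequency) %in% x$retained,
    mean_sign = unname(x$mean_sign[names(x$frequency)])
  ), path, row.names = FALSE)
  invisible(path)
}
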