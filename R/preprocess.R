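#' Stratified train/test split with largest-remainder test allocation
#'
#' The total test-set size is the ceiling of `test_fraction * n`; per-stratum
#' test counts start at the floor of each stratum's exact quota
#' `test_fraction * n_stratum` and the remaining seats go to the strata with
#' the largest fractional remainders. This convention makes each stratum's
#' test count deviate from its exact quota by less than one subject (for a
#' 112 + 50 cohort at 8:2 it yields the 129-train / 33-test split, with
#' 23 + 10 in the test set). Membership within a stratum is random given the
#' seed.
#'
#' @param labels Vector of stratum labels, one per subject.
#' @param test_fraction Fraction of subjects held out (default 0.2).
#' @param seed Integer seed.
#' @return Object of class `split_plan`: `train` and `test` index vectors,
#'   `stratum_counts` (matrix of train/test counts per stratum), `seed`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 strata")
  if (any(tab < 2)) {
    stop("stratum too small to split: ", paste(names(tab)[tab < 2], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  quota <- as.numeric(tab) * test_fraction
  total <- as.integer(ceiling(sum(quota) - 1e-9))
  base <- floor(quota + 1e-9)
  remainder <- quota - base
  leftover <- total - sum(base)
  counts <- base
  if (leftover > 0) {
    take <- order(remainder, as.numeric(tab), decreasing = TRUE)[seq_len(leftover)]
    counts[take] <- counts[take] + 1
  }
  names(counts) <- names(tab)
  test_idx <- integer(0)
  for (s in names(tab)) {
    members <- which(labels == s)
    test_idx <- c(test_idx, sample(members, counts[[s]]))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(labels), test_idx)
  structure(list(
    train = train_idx, test = test_idx,
    stratum_counts = rbind(train = as.integer(tab) - counts, test = counts),
    seed = seed
  ), class = "split_plan")
}

#' Stratified k-fold assignment
#'
#' Within each class, subjects are shuffled and dealt so that per-fold class
#' counts differ by at most one; which folds receive the extra members is
#' itself randomized.
#'
#' @param labels Class labels, one per subject.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k aligned with `labels`, with
#'   class `fold_assignment` and attributes `k` and `seed`.
#' @export
assign_folds <- function(labels, k = 5, seed = NULL) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("class smaller than k: ", paste(names(tab)[tab < k], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (s in names(tab)) {
    members <- sample(which(labels == s))
    n <- length(members)
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) {
      lucky <- sample(k, extra)
      sizes[lucky] <- sizes[lucky] + 1L
    }
    fold[members] <- rep(seq_len(k), times = sizes)
  }
  structure(fold, class = "fold_assignment", k = k, seed = seed)
}

#' Fit a leakage-safe z-score standardizer on training data
#'
#' Column means and sample standard deviations (denominator n - 1) are
#' estimated on the training rows only, ignoring missing cells; zero-variance
#' columns are dropped with a warning. The fitted parameters are then reused
#' verbatim on validation or test data via [apply_standardizer()] — never
#' refit.
#'
#' @param x Numeric matrix or data frame of training features.
#' @return Object of class `standardizer`: `center`, `scale`, `keep`
#'   (retained column names), `dropped`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0)) {
    stop("all-missing column(s): ", paste(colnames(x)[n_obs == 0], collapse = ", "))
  }
  center <- colMeans(x, na.rm = TRUE)
  scale <- apply(x, 2, stats::sd, na.rm = TRUE)
  constant <- !is.finite(scale) | scale == 0
  if (any(constant)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[constant], collapse = ", "))
  }
  keep <- colnames(x)[!constant]
  structure(list(center = center[keep], scale = scale[keep], keep = keep,
                 dropped = colnames(x)[constant]),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params A fitted `standardizer`.
#' @export
apply_standardizer <- function(params, x) {
  x <- as.matrix(x)
  missing <- setdiff(params$keep, colnames(x))
  if (length(missing) > 0) {
    stop("features absent from data: ", paste(missing, collapse = ", "))
  }
  x <- x[, params$keep, drop = FALSE]
  sweep(sweep(x, 2, params$center, `-`), 2, params$scale, `/`)
}

#' Serialize a split plan or fold assignment to JSON
#'
#' @param x A `split_plan` or `fold_assignment`.
#' @param path File path.
#' @export
write_plan_json <- function(x, path) {
  if (inherits(x, "split_plan")) {
    jsonlite::write_json(list(train = x$train, test = x$test, seed = x$seed),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  } else if (inherits(x, "fold_assignment")) {
    jsonlite::write_json(list(fold = as.integer(x), k = attr(x, "k"),
                              seed = attr(x, "seed")),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  } else stop("unsupported object")
  invisible(path)
}
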