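# coerce labels + designated positive class to a logical indicator
pos_indicator <- function(labels, positive) {
  if (is.logical(labels)) return(labels)
  if (missing(positive) || is.null(positive)) {
    stop("`positive` must name the positive class for non-logical labels")
  }
  as.character(labels) == as.character(positive)
}

# orient scores so that larger means "more positive"
orient_scores <- function(scores, direction) {
  direction <- match.arg(direction, c(">", "<"))
  if (direction == "<") -scores else scores
}

#' Mann-Whitney AUC of a score or marker
#'
#' The empirical AUC: the proportion of positive-negative pairs in which the
#' (orientation-adjusted) positive score exceeds the negative one, with ties
#' counting one half. Computed via mid-ranks.
#'
#' @param scores Numeric scores or marker values.
#' @param labels Class labels (logical, or any vector plus `positive`).
#' @param positive The positive class label.
#' @param direction `">"` if high scores indicate the positive class (default),
#'   `"<"` if low values do.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels, positive = NULL, direction = ">") {
  pos <- pos_indicator(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- orient_scores(scores[keep], direction)
  pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# placement values: for each positive, the fraction of negatives it beats
# (ties half), and vice versa — the structural components of the DeLong
# variance estimator
placement_values <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong confidence interval for a single AUC
#'
#' Nonparametric variance from the placement-value (structural component)
#' covariance estimator; the Wald interval AUC +/- z * SE is truncated to
#' \[0, 1\]. Perfectly separated data have constant placement values, SE 0 and
#' a zero-width interval.
#'
#' @inheritParams auc_mann_whitney
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `se`, `lower`, `upper`, `level`.
#' @export
delong_ci <- function(scores, labels, positive = NULL, direction = ">",
                      level = 0.95) {
  pos <- pos_indicator(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  s <- orient_scores(scores[keep], direction)
  pos <- pos[keep]
  if (sum(pos) < 2 || sum(!pos) < 2) stop("need at least 2 members per class")
  auc <- auc_mann_whitney(s, pos)
  pv <- placement_values(s, pos)
  se <- sqrt(stats::var(pv$v10) / length(pv$v10) +
             stats::var(pv$v01) / length(pv$v01))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = auc, se = se,
       lower = max(0, auc - z * se), upper = min(1, auc + z * se),
       level = level)
}

#' Youden-optimal cutoff for a single marker
#'
#' Candidate cutoffs are midpoints between consecutive distinct observed
#' values; the cutoff maximizing J = sensitivity + specificity - 1 is
#' returned, with ties in J broken toward higher specificity. The cutoff is
#' reported in original marker units; for `direction = "<"` the decision rule
#' is "marker <= cutoff indicates the positive class".
#'
#' @inheritParams auc_mann_whitney
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden`,
#'   `direction`.
#' @export
youden_cutoff <- function(scores, labels, positive = NULL, direction = ">") {
  pos <- pos_indicator(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  s <- orient_scores(scores[keep], direction)
  pos <- pos[keep]
  if (sum(pos) == 0 || sum(!pos) == 0) stop("both classes must be present")
  u <- sort(unique(s))
  if (length(u) == 1) {
    cut0 <- if (direction == "<") -u else u
    return(list(cutoff = cut0, sensitivity = 1, specificity = 0, youden = 0,
                direction = direction))
  }
  mids <- (u[-1] + u[-length(u)]) / 2
  best <- list(j = -Inf, spec = -Inf, cut = NA_real_, sens = NA_real_)
  for (t in mids) {
    call_pos <- s >= t
    sens <- mean(call_pos[pos])
    spec <- mean(!call_pos[!pos])
    j <- sens + spec - 1
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(j = j, spec = spec, cut = t, sens = sens)
    }
  }
  cutoff <- if (direction == "<") -best$cut else best$cut
  list(cutoff = cutoff, sensitivity = best$sens, specificity = best$spec,
       youden = best$j, direction = direction)
}

#' Stratified bootstrap percentile interval for an AUC
#'
#' Resamples within each class with replacement and reports the 2.5/97.5
#' percentile interval of the bootstrap AUC distribution.
#'
#' @inheritParams auc_mann_whitney
#' @param B Number of bootstrap resamples (default 2000).
#' @param stratified Resample within class (default TRUE).
#' @param seed Integer seed.
#' @return List with `interval` (length 2), `B`, and the bootstrap `aucs`.
#' @export
bootstrap_auc <- function(scores, labels, positive = NULL, direction = ">",
                          B = 2000, stratified = TRUE, seed = NULL) {
  pos <- pos_indicator(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  s <- orient_scores(scores[keep], direction)
  pos <- pos[keep]
  if (!is.null(seed)) set.seed(as.integer(seed))
  ip <- which(pos); ineg <- which(!pos)
  aucs <- vapply(seq_len(B), function(b) {
    idx <- if (stratified) {
      c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    } else {
      sample(seq_along(s), replace = TRUE)
    }
    if (length(unique(pos[idx])) < 2) return(NA_real_)
    auc_mann_whitney(s[idx], pos[idx])
  }, numeric(1))
  list(interval = unname(stats::quantile(aucs, c(0.025, 0.975), na.rm = TRUE)),
       B = B, aucs = aucs)
}

#' Label-permutation test for an AUC
#'
#' Permutes class labels B times and reports the add-one-corrected one-sided
#' p-value `p = (1 + #\{AUC_perm >= AUC_obs\}) / (B + 1)`; p can never be 0,
#' and with zero exceedances at B = 5000 the floor is 1/5001 (about 2e-4).
#'
#' @inheritParams auc_mann_whitney
#' @param B Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return List with `p`, `observed`, `exceedances`, `B`.
#' @export
permutation_test <- function(scores, labels, positive = NULL, direction = ">",
                             B = 5000, seed = NULL) {
  pos <- pos_indicator(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  s <- orient_scores(scores[keep], direction)
  pos <- pos[keep]
  observed <- auc_mann_whitney(s, pos)
  if (!is.null(seed)) set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(B)) {
    if (auc_mann_whitney(s, sample(pos)) >= observed - 1e-12) exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (B + 1), observed = observed,
       exceedances = exceed, B = B)
}

#' Repeated stratified holdout AUC range for a single marker
#'
#' Draws repeated stratified 20/80 splits and reports the 2.5/97.5 percentile
#' range of the held-out AUCs.
#'
#' @inheritParams auc_mann_whitney
#' @param repeats Number of random splits (default 1000).
#' @param test_fraction Held-out fraction per repeat (default 0.2).
#' @param seed Integer seed.
#' @return List with `range` (length 2), `repeats`, `aucs`.
#' @export
repeated_holdout_auc <- function(scores, labels, positive = NULL,
                                 direction = ">", repeats = 1000,
                                 test_fraction = 0.2, seed = NULL) {
  pos <- pos_indicator(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  s <- orient_scores(scores[keep], direction)
  pos <- pos[keep]
  if (sum(pos) < 5 || sum(!pos) < 5) stop("need at least 5 members per class")
  if (!is.null(seed)) set.seed(as.integer(seed))
  aucs <- vapply(seq_len(repeats), function(r) {
    plan <- stratified_split(pos, test_fraction = test_fraction)
    auc_mann_whitney(s[plan$test], pos[plan$test])
  }, numeric(1))
  list(range = unname(stats::quantile(aucs, c(0.025, 0.975))),
       repeats = repeats, aucs = aucs)
}

#' Repeated stratified k-fold AUC interval for a single marker
#'
#' For each repetition a fresh stratified fold assignment is drawn; the mean
#' of the k held-out fold AUCs is recorded and the 2.5/97.5 percentile
#' interval of these per-repetition means is reported. Averaging across folds
#' shrinks the interval relative to single holdouts.
#'
#' @inheritParams auc_mann_whitney
#' @param k Folds per repetition (default 5).
#' @param repetitions Number of repetitions (default 200).
#' @param seed Integer seed.
#' @return List with `interval`, `repetitions`, `mean_aucs`.
#' @export
repeated_kfold_auc <- function(scores, labels, positive = NULL, direction = ">",
                               k = 5, repetitions = 200, seed = NULL) {
  pos <- pos_indicator(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  s <- orient_scores(scores[keep], direction)
  pos <- pos[keep]
  if (sum(pos) < k || sum(!pos) < k) stop("need at least k members per class")
  if (!is.null(seed)) set.seed(as.integer(seed))
  means <- vapply(seq_len(repetitions), function(r) {
    fold <- assign_folds(pos, k = k)
    mean(vapply(seq_len(k), function(f) {
      auc_mann_whitney(s[fold == f], pos[fold == f])
    }, numeric(1)))
  }, numeric(1))
  list(interval = unname(stats::quantile(means, c(0.025, 0.975))),
       repetitions = repetitions, mean_aucs = means)
}

#' Full single-marker robustness suite
#'
#' Bundles the point AUC with DeLong interval, Youden cutoff, stratified
#' bootstrap percentile interval, label-permutation p, repeated stratified
#' holdout range and repeated stratified k-fold interval for one marker —
#' the reporting block used for a candidate diagnostic metabolite.
#'
#' @inheritParams auc_mann_whitney
#' @param B_boot,B_perm,holdout_repeats,kfold_repetitions,kfold_k Resampling
#'   sizes (defaults 2000 / 5000 / 1000 / 200 / 5).
#' @param seed Integer seed driving all resampling.
#' @return Object of class `marker_inference`.
#' @export
marker_inference <- function(scores, labels, positive = NULL, direction = ">",
                             B_boot = 2000, B_perm = 5000,
                             holdout_repeats = 1000, kfold_repetitions = 200,
                             kfold_k = 5, seed = NULL) {
  dl <- delong_ci(scores, labels, positive, direction)
  yc <- youden_cutoff(scores, labels, positive, direction)
  bt <- bootstrap_auc(scores, labels, positive, direction, B = B_boot,
                      seed = if (is.null(seed)) NULL else seed + 1L)
  pm <- permutation_test(scores, labels, positive, direction, B = B_perm,
                         seed = if (is.null(seed)) NULL else seed + 2L)
  ho <- repeated_holdout_auc(scores, labels, positive, direction,
                             repeats = holdout_repeats,
                             seed = if (is.null(seed)) NULL else seed + 3L)
  kf <- repeated_kfold_auc(scores, labels, positive, direction, k = kfold_k,
                           repetitions = kfold_repetitions,
                           seed = if (is.null(seed)) NULL else seed + 4L)
  structure(list(auc = dl$auc, delong = dl, youden = yc,
                 bootstrap = bt[c("interval", "B")],
                 permutation = pm, holdout = ho[c("range", "repeats")],
                 kfold = kf[c("interval", "repetitions")],
                 direction = direction, seed = seed),
            class = "marker_inference")
}

#' @export
print.marker_inference <- function(x, ...) {
  cat(sprintf("AUC %.3f (DeLong %d%% CI %.3f-%.3f)\n", x$auc,
              round(100 * x$delong$level), x$delong$lower, x$delong$upper))
  rule <- if (x$direction == "<") "<=" else ">="
  cat(sprintf("Youden cutoff: marker %s %.4g (sens %.3f, spec %.3f, J %.3f)\n",
              rule, x$youden$cutoff, x$youden$sensitivity,
              x$youden$specificity, x$youden$youden))
  cat(sprintf("Stratified bootstrap (B = %d) 95%% interval %.3f-%.3f\n",
              x$bootstrap$B, x$bootstrap$interval[1], x$bootstrap$interval[2]))
  cat(sprintf("Permutation test (B = %d) one-sided p = %.4g\n",
              x$permutation$B, x$permutation$p))
  cat(sprintf("Repeated holdout (%d repeats) 95%% range %.3f-%.3f\n",
              x$holdout$repeats, x$holdout$range[1], x$holdout$range[2]))
  cat(sprintf("Repeated %d-fold CV (%d repetitions) 95%% interval %.3f-%.3f\n",
              5, x$kfold$repetitions, x$kfold$interval[1], x$kfold$interval[2]))
  invisible(x)
}

#' Serialize a marker inference block to JSON
#'
#' @param x A `marker_inference`.
#' @param path File path.
#' @export
write_marker_json <- function(x, path) {
  jsonlite::write_json(list(
    auc = x$auc,
    delong_ci = c(x$delong$lower, x$delong$upper),
    youden = x$youden[c("cutoff", "sensitivity", "specificity", "youden")],
    bootstrap_interval = x$bootstrap$interval, bootstrap_B = x$bootstrap$B,
    permutation_p = x$permutation$p, permutation_B = x$permutation$B,
    holdout_range = x$holdout$range, kfold_interval = x$kfold$interval
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
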