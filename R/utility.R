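#' Decision-curve analysis (net benefit across decision thresholds)
#'
#' Net benefit at threshold probability p_t is
#' `TP/n - (FP/n) * p_t / (1 - p_t)` under the rule "call positive when the
#' predicted probability is at least p_t". Treat-all and treat-none reference
#' strategies are returned alongside; treat-all crosses zero at
#' p_t = prevalence.
#'
#' @param probabilities Predicted positive-class probabilities in \[0, 1\].
#' @param labels Class labels.
#' @param positive Positive class label.
#' @param thresholds Threshold grid (default 0.01 to 0.99 step 0.01; 1 is
#'   excluded by construction).
#' @return Object of class `net_benefit_curve`: data frame with columns
#'   `threshold`, `net_benefit`, `treat_all`, `treat_none`, plus attribute
#'   `prevalence`.
#' @export
decision_curve <- function(probabilities, labels, positive = NULL,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1),
            all(thresholds > 0 & thresholds < 1))
  pos <- pos_indicator(labels, positive)
  n <- length(pos)
  prev <- mean(pos)
  nb <- vapply(thresholds, function(pt) {
    call_pos <- probabilities >= pt
    sum(call_pos & pos) / n - sum(call_pos & !pos) / n * pt / (1 - pt)
  }, numeric(1))
  treat_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  out <- data.frame(threshold = thresholds, net_benefit = nb,
                    treat_all = treat_all, treat_none = 0)
  attr(out, "prevalence") <- prev
  class(out) <- c("net_benefit_curve", class(out))
  out
}

#' Category-free (continuous) net reclassification improvement
#'
#' Event NRI = P(new > old | event) - P(new < old | event); non-event
#' NRI = P(new < old | non-event) - P(new > old | non-event); overall NRI is
#' their sum. Positive values mean the comparator model moves events up and
#' non-events down relative to the baseline.
#'
#' @param old_probs Baseline-model probabilities.
#' @param new_probs Comparator-model probabilities.
#' @param labels Class labels.
#' @param positive Positive (event) class label.
#' @return List with `overall`, `event`, `non_event`.
#' @export
nri_continuous <- function(old_probs, new_probs, labels, positive = NULL) {
  stopifnot(length(old_probs) == length(new_probs))
  pos <- pos_indicator(labels, positive)
  if (sum(pos) == 0 || sum(!pos) == 0) stop("need both events and non-events")
  up <- new_probs > old_probs
  down <- new_probs < old_probs
  event <- mean(up[pos]) - mean(down[pos])
  non_event <- mean(down[!pos]) - mean(up[!pos])
  list(overall = event + non_event, event = event, non_event = non_event)
}

#' Integrated discrimination improvement
#'
#' IDI = \[mean(new | event) - mean(new | non-event)\] -
#' \[mean(old | event) - mean(old | non-event)\]: the change in the
#' discrimination slope. Antisymmetric in its model arguments.
#'
#' @inheritParams nri_continuous
#' @return Single numeric IDI.
#' @export
idi <- function(old_probs, new_probs, labels, positive = NULL) {
  stopifnot(length(old_probs) == length(new_probs))
  pos <- pos_indicator(labels, positive)
  if (sum(pos) == 0 || sum(!pos) == 0) stop("need both events and non-events")
  (mean(new_probs[pos]) - mean(new_probs[!pos])) -
    (mean(old_probs[pos]) - mean(old_probs[!pos]))
}

#' Friedman test over a models-by-blocks AUC matrix with Holm post-hoc
#'
#' Global comparison of model AUCs across matched blocks (cross-validation
#' folds) via the Friedman rank test (average ranks on ties). When the global
#' test is significant, all pairwise paired t-tests on matched bootstrap AUC
#' samples are run and adjusted by the Holm step-down procedure.
#'
#' @param auc_matrix Numeric matrix, models x blocks.
#' @param boot_pairs Optional models x B matrix of matched bootstrap AUCs for
#'   the post-hoc tests.
#' @param alpha Significance gate for running post-hoc tests (default 0.05).
#' @return Object of class `model_comparison`: `statistic`, `df`, `p_value`,
#'   and (when run) a `pairwise` data frame with raw and Holm-adjusted p.
#' @export
friedman_with_holm <- function(auc_matrix, boot_pairs = NULL, alpha = 0.05) {
  stopifnot(is.matrix(auc_matrix), nrow(auc_matrix) >= 3,
            ncol(auc_matrix) >= 2)
  if (all(auc_matrix == auc_matrix[1])) {
    ft <- list(statistic = 0, parameter = nrow(auc_matrix) - 1, p.value = 1)
  } else {
    test <- stats::friedman.test(t(auc_matrix))
    ft <- list(statistic = unname(test$statistic),
               parameter = unname(test$parameter), p.value = test$p.value)
  }
  pairwise <- NULL
  if (ft$p.value < alpha && !is.null(boot_pairs)) {
    models <- rownames(boot_pairs)
    combs <- utils::combn(models, 2)
    raw <- apply(combs, 2, function(pair) {
      stats::t.test(boot_pairs[pair[1], ], boot_pairs[pair[2], ],
                    paired = TRUE)$p.value
    })
    pairwise <- data.frame(model_a = combs[1, ], model_b = combs[2, ],
                           p_raw = raw,
                           p_holm = stats::p.adjust(raw, method = "holm"))
  }
  structure(list(statistic = ft$statistic, df = ft$parameter,
                 p_value = ft$p.value, pairwise = pairwise),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("Holm-adjusted pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
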