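#' Run the full biomarker discovery pipeline
#'
#' Orchestrates the end-to-end analysis on a cohort (synthetic by default):
#' index catalogue evaluation, stratified 8:2 split of the NMOSD-vs-MS task,
#' training-set z-score standardization reused verbatim on the test set,
#' stability selection via nested cross-validated LASSO, the multi-classifier
#' benchmark under three-level validation, the single-marker robustness suite
#' (default: DCA for seronegative NMOSD vs MS, low values indicating NMOSD),
#' clinical-utility statistics against the stable-features logistic baseline,
#' and group-level descriptive statistics.
#'
#' @param cohort Subject-level data frame (see [build_feature_table()]); when
#'   `NULL` a synthetic cohort is generated from `config`.
#' @param config A [cohort_config()] used when `cohort` is `NULL`.
#' @param seed Integer seed driving every stage.
#' @param marker Analyte for the single-marker robustness suite
#'   (default `"DCA"`).
#' @param marker_groups Two group labels for the marker task, positive first
#'   (default seronegative NMOSD vs MS).
#' @param marker_direction `"<"` when low marker values indicate the positive
#'   class (the default, matching secondary bile-acid suppression).
#' @param model_kinds Benchmark classifiers to train.
#' @param reps,cv_k Repeated-CV shape for validation (defaults 10 and 5).
#' @param boot_B,perm_B,holdout_repeats,kfold_repetitions Resampling sizes.
#' @param out_dir Optional directory for CSV/JSON reports.
#' @return Object of class `ba_pipeline` collecting every stage's result.
#' @export
run_pipeline <- function(cohort = NULL, config = default_cohort_config(),
                         seed = 1, marker = "DCA",
                         marker_groups = c("NMOSD_AQP4neg", "MS"),
                         marker_direction = "<",
                         model_kinds = c(logistic_stable = "logistic",
                                         random_forest = "random_forest",
                                         svm_linear = "svm_linear",
                                         gbt = "gbt",
                                         lasso_logistic = "lasso_logistic"),
                         reps = 10, cv_k = 5, boot_B = 1000, perm_B = 5000,
                         holdout_repeats = 1000, kfold_repetitions = 200,
                         out_dir = NULL) {
  seed <- as.integer(seed)
  if (is.null(cohort)) cohort <- generate_cohort(config, seed = seed)
  ft <- build_feature_table(cohort)
  idx_names <- attr(ft, "index_names")

  # --- NMOSD-vs-MS task: split, standardize, select, benchmark -------------
  is_task <- grepl("^NMOSD", as.character(ft$group)) |
    as.character(ft$group) == "MS"
  task <- ft[is_task, , drop = FALSE]
  y <- factor(ifelse(grepl("^NMOSD", as.character(task$group)), "NMOSD", "MS"),
              levels = c("MS", "NMOSD"))
  plan <- stratified_split(y, test_fraction = 0.2, seed = seed + 11L)
  x_all <- as.matrix(task[, idx_names, drop = FALSE])
  std <- suppressWarnings(fit_standardizer(x_all[plan$train, , drop = FALSE]))
  x_train <- apply_standardizer(std, x_all[plan$train, , drop = FALSE])
  x_test <- apply_standardizer(std, x_all[plan$test, , drop = FALSE])
  # penalized fits cannot take missing cells: impute at the training mean
  # (zero on the standardized scale), the neutral value under z-scoring
  x_train[is.na(x_train)] <- 0
  x_test[is.na(x_test)] <- 0
  y_train <- y[plan$train]
  y_test <- y[plan$test]

  stability <- nested_stability_selection(x_train, y_train, positive = "NMOSD",
                                          seed = seed + 23L)
  stable_feats <- stability$retained
  if (length(stable_feats) == 0) stable_feats <- colnames(x_train)

  models <- list()
  for (m in names(model_kinds)) {
    kind <- model_kinds[[m]]
    feats <- if (kind == "lasso_logistic") colnames(x_train) else stable_feats
    models[[m]] <- train_model(kind, x_train, y_train, positive = "NMOSD",
                               features = feats, seed = seed + 31L)
  }
  validation <- three_level_validation(models, x_train, y_train, x_test,
                                       y_test, positive = "NMOSD",
                                       reps = reps, k = cv_k, boot_B = boot_B,
                                       seed = seed + 41L)
  logistic_summary <- if ("logistic_stable" %in% names(models)) {
    summarize_logistic(models[["logistic_stable"]])
  } else NULL

  # --- clinical utility against the stable-features logistic baseline ------
  baseline_name <- names(models)[1]
  test_probs <- lapply(models, predict_prob, newx = x_test)
  utility <- list(
    decision_curves = lapply(test_probs, decision_curve, labels = y_test,
                             positive = "NMOSD"),
    reclassification = lapply(
      setdiff(names(models), baseline_name),
      function(m) c(list(baseline = baseline_name, comparator = m),
                    nri_continuous(test_probs[[baseline_name]],
                                   test_probs[[m]], y_test, "NMOSD"),
                    list(idi = idi(test_probs[[baseline_name]],
                                   test_probs[[m]], y_test, "NMOSD")))),
    comparison = friedman_with_holm(validation$cv_auc_matrix,
                                    validation$boot_auc_matrix)
  )

  # --- single-marker robustness suite --------------------------------------
  in_marker <- as.character(ft$group) %in% marker_groups
  marker_inf <- marker_inference(
    scores = ft[[marker]][in_marker],
    labels = as.character(ft$group)[in_marker], positive = marker_groups[1],
    direction = marker_direction, B_boot = 2000, B_perm = perm_B,
    holdout_repeats = holdout_repeats, kfold_repetitions = kfold_repetitions,
    seed = seed + 51L)

  # --- cohort-level statistics ---------------------------------------------
  pca <- pca_scores(local({
    m <- as.matrix(ft[, idx_names, drop = FALSE])
    m[, apply(m, 2, function(v) !anyNA(v) && stats::sd(v) > 0), drop = FALSE]
  }))
  kw_table <- group_index_tests(ft)
  edss_cor <- lapply(stats::setNames(nm = intersect(
    c("NMOSD_AQP4pos", "NMOSD_AQP4neg", "MS"), unique(as.character(ft$group)))),
    function(g) {
      rows <- as.character(ft$group) == g & !is.na(ft$EDSS)
      if (sum(rows) < 3) return(NULL)
      lapply(stats::setNames(nm = c("DCA", "LCA", "UDCAs")), function(v) {
        spearman_cor(ft[[v]][rows], ft$EDSS[rows])
      })
    })

  result <- structure(list(
    feature_table = ft, split = plan, standardizer = std,
    stability = stability, models = models, validation = validation,
    logistic_summary = logistic_summary, utility = utility,
    marker = list(name = marker, groups = marker_groups,
                  direction = marker_direction, inference = marker_inf),
    cohort_stats = list(pca = pca, kw_table = kw_table, edss_cor = edss_cor),
    seed = seed
  ), class = "ba_pipeline")
  if (!is.null(out_dir)) write_pipeline_report(result, out_dir)
  result
}

#' @export
print.ba_pipeline <- function(x, ...) {
  cat("Bile-acid biomarker discovery pipeline (seed", x$seed, ")\n")
  cat(sprintf("Cohort: %d subjects, %d derived indices (%d missing cells)\n",
              nrow(x$feature_table),
              length(attr(x$feature_table, "index_names")),
              attr(x$feature_table, "n_missing")))
  cat(sprintf("NMOSD-vs-MS split: %d train / %d test\n",
              length(x$split$train), length(x$split$test)))
  print(x$stability)
  print(x$validation)
  cat(sprintf("\nMarker suite: %s, %s vs %s\n", x$marker$name,
              x$marker$groups[1], x$marker$groups[2]))
  print(x$marker$inference)
  invisible(x)
}

#' Write the pipeline report bundle to a directory
#'
#' Emits the feature table, stability CSV, benchmark metric panel (both
#' threshold conventions), logistic coefficient table, decision curves,
#' reclassification JSON, marker inference JSON and the split plan, plus a
#' provenance JSON with the seed.
#'
#' @param x A `ba_pipeline`.
#' @param dir Output directory (created if absent).
#' @export
write_pipeline_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$feature_table, file.path(dir, "feature_table.csv"),
                   row.names = FALSE)
  write_stability_csv(x$stability, file.path(dir, "stability.csv"))
  panel <- do.call(rbind, lapply(names(x$validation$models), function(m) {
    s <- x$validation$models[[m]]
    h <- s$holdout_best
    data.frame(model = m, auc = h$auc, auc_lo = h$auc_ci[1],
               auc_hi = h$auc_ci[2], accuracy = h$accuracy,
               balanced_accuracy = h$balanced_accuracy,
               sensitivity = h$sensitivity, specificity = h$specificity,
               f1 = h$f1, youden = h$youden, best_threshold = h$threshold,
               accuracy_at_05 = s$holdout_05$accuracy,
               cv_mean_auc = s$cv_mean, cv_sd_auc = s$cv_sd,
               cv_coefficient = s$cv_coefficient,
               boot_lo = s$boot_interval[1], boot_hi = s$boot_interval[2])
  }))
  utils::write.csv(panel, file.path(dir, "metric_panel.csv"), row.names = FALSE)
  if (!is.null(x$logistic_summary)) {
    utils::write.csv(x$logistic_summary,
                     file.path(dir, "logistic_summary.csv"), row.names = FALSE)
  }
  write_marker_json(x$marker$inference, file.path(dir, "marker_inference.json"))
  write_plan_json(x$split, file.path(dir, "split_plan.json"))
  jsonlite::write_json(x$utility$reclassification,
                       file.path(dir, "reclassification.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(seed = x$seed), file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
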