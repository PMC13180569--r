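#' Kruskal-Wallis test across groups
#'
#' Rank-based H test with tie correction and a chi-squared reference
#' distribution on k - 1 degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels aligned with `values` (or a list of numeric
#'   vectors, in which case `groups` is ignored).
#' @return List with `statistic`, `df`, `p_value`, `test`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values)) {
    if (any(lengths(values) == 0)) stop("empty group")
    kt <- stats::kruskal.test(values)
  } else {
    if (any(table(groups) == 0)) stop("empty group")
    keep <- !is.na(values)
    kt <- stats::kruskal.test(values[keep], factor(as.character(groups[keep])))
  }
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, test = "Kruskal-Wallis")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with p-value from the asymptotic t
#' approximation; missing pairs are dropped. A variable with zero rank
#' variance yields an NA correlation with a flag rather than an error.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho`, `p_value`, `n`, `defined`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n, defined = TRUE)
}

#' Principal component analysis of a feature matrix
#'
#' Correlation-scale PCA (columns centered and scaled) by default, matching
#' the z-score convention used elsewhere in the pipeline.
#'
#' @param x Numeric matrix or data frame (subjects x features).
#' @param n_components Number of components to retain.
#' @param scale. Scale columns to unit variance (default TRUE).
#' @return Object of class `ba_pca`: `loadings` (orthonormal columns),
#'   `scores`, `explained` (variance fractions, non-increasing).
#' @export
pca_scores <- function(x, n_components = 2, scale. = TRUE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  rank_x <- sum(pc$sdev > 1e-10)
  if (n_components > rank_x) {
    warning("n_components exceeds rank (", rank_x, "); truncating")
    n_components <- rank_x
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 scores = pc$x[, seq_len(n_components), drop = FALSE],
                 explained = explained[seq_len(n_components)]),
            class = "ba_pca")
}

#' Per-index group comparison table
#'
#' Kruskal-Wallis test for every catalogue index across the cohort groups,
#' with Benjamini-Hochberg FDR reported alongside the raw p-values.
#'
#' @param feature_table A `ba_feature_table` from [build_feature_table()].
#' @param groups Optional subset of group labels to compare (default all).
#' @return Data frame with columns `index`, `statistic`, `df`, `p_value`,
#'   `fdr`.
#' @export
group_index_tests <- function(feature_table, groups = NULL) {
  idx_names <- attr(feature_table, "index_names")
  g <- as.character(feature_table$group)
  keep <- if (is.null(groups)) rep(TRUE, nrow(feature_table)) else g %in% groups
  res <- lapply(idx_names, function(j) {
    v <- feature_table[[j]][keep]
    ok <- !is.na(v)
    if (length(unique(g[keep][ok])) < 2) {
      return(data.frame(index = j, statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_))
    }
    kw <- kruskal_wallis(v[ok], g[keep][ok])
    data.frame(index = j, statistic = kw$statistic, df = kw$df,
               p_value = kw$p_value)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}
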