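# Independent oracles, deliberately coded from scratch in a different style
# from the package internals (indicator matrices and pair loops rather than
# membership lists and ranks), so agreement is informative.

# analyte-by-pool 0/1 indicator matrix, re-typed from the pool definitions
oracle_pool_matrix <- function() {
  a <- c("TCA", "TCDCA", "GCA", "GCDCA", "CDCA", "CA", "DCA", "GDCA", "TDCA",
         "LCA", "GLCA", "TLCA", "UDCA", "GUDCA", "TUDCA")
  m <- matrix(0L, nrow = 15, ncol = 17, dimnames = list(a, c(
    "primary", "secondary", "TBA", "conjugated", "unconjugated",
    "G_conjugated", "T_conjugated", "OH12", "non_OH12", "CAs", "CDCAs",
    "DCAs", "LCAs", "UDCAs", "neurotoxic", "neuroprotective",
    "conjugated_UDCAs")))
  m[c("TCA", "TCDCA", "GCA", "GCDCA", "CDCA", "CA"), "primary"] <- 1L
  m[c("DCA", "GDCA", "TDCA", "LCA", "GLCA", "TLCA", "UDCA", "GUDCA",
      "TUDCA"), "secondary"] <- 1L
  m[, "TBA"] <- 1L
  m[c("TCA", "TCDCA", "GCA", "GCDCA"), "conjugated"] <- 1L
  m[c("CA", "CDCA", "DCA", "LCA", "UDCA"), "unconjugated"] <- 1L
  m[c("GCA", "GCDCA", "GDCA", "GLCA", "GUDCA"), "G_conjugated"] <- 1L
  m[c("TCA", "TCDCA", "TDCA", "TLCA", "TUDCA"), "T_conjugated"] <- 1L
  m[c("CA", "TCA", "GCA", "DCA", "TDCA", "GDCA"), "OH12"] <- 1L
  m[c("CDCA", "TCDCA", "GCDCA", "LCA", "TLCA", "GLCA", "UDCA", "GUDCA",
      "TUDCA"), "non_OH12"] <- 1L
  m[c("GCA", "TCA", "CA"), "CAs"] <- 1L
  m[c("GCDCA", "TCDCA", "CDCA"), "CDCAs"] <- 1L
  m[c("GDCA", "TDCA", "DCA"), "DCAs"] <- 1L
  m[c("GLCA", "TLCA", "LCA"), "LCAs"] <- 1L
  m[c("GUDCA", "TUDCA", "UDCA"), "UDCAs"] <- 1L
  m[c("GCA", "GCDCA", "GDCA"), "neurotoxic"] <- 1L
  m[c("GUDCA", "TUDCA", "UDCA"), "neuroprotective"] <- 1L
  m[c("GUDCA", "TUDCA"), "conjugated_UDCAs"] <- 1L
  m
}

# brute-force evaluation of every index for one profile vector
oracle_indices <- function(profile) {
  m <- oracle_pool_matrix()
  profile <- profile[rownames(m)]
  pools <- as.numeric(profile %*% m)
  names(pools) <- colnames(m)
  tba <- pools[["TBA"]]
  pct <- function(v) if (tba == 0) NA_real_ else v / tba
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(profile, pools,
           setNames(vapply(profile, pct, numeric(1)),
                    paste0("pct_", names(profile))),
           setNames(vapply(pools[setdiff(names(pools), "TBA")], pct,
                           numeric(1)),
                    paste0("pct_", setdiff(names(pools), "TBA"))),
           OH12_over_nonOH12 = rat(pools[["OH12"]], pools[["non_OH12"]]),
           GLCA_over_TLCA = rat(profile[["GLCA"]], profile[["TLCA"]]),
           GDCA_over_TDCA = rat(profile[["GDCA"]], profile[["TDCA"]]),
           primary_over_secondary = rat(pools[["primary"]],
                                        pools[["secondary"]]),
           conjugated_over_unconjugated = rat(pools[["conjugated"]],
                                              pools[["unconjugated"]]),
           Gconj_over_Tconj = rat(pools[["G_conjugated"]],
                                  pools[["T_conjugated"]]),
           neurotoxic_over_neuroprotective = rat(pools[["neurotoxic"]],
                                                 pools[["neuroprotective"]]),
           CAs_over_CDCAs = rat(pools[["CAs"]], pools[["CDCAs"]]))
  out
}

# pair-counting AUC oracle: explicit double loop over positive-negative pairs
oracle_auc_pairs <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  total <- 0
  for (xi in x) for (yj in y) {
    total <- total + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  total / (length(x) * length(y))
}

# random valid profile on a positive scale
random_profile <- function() {
  setNames(round(10^runif(15, -3, 1), 6), bilemarkers::ba_analytes())
}

# two-group cohort data frame with a planted standardized log10 shift on one
# analyte, mirroring the generator's binormal parameterization
planted_two_group_cohort <- function(n_pos = 32, n_neg = 50, analyte = "DCA",
                                     d = 2.56) {
  cfg0 <- bilemarkers::default_cohort_config()
  groups <- c("NMOSD_AQP4neg", "MS")
  delta <- cfg0$delta[groups, , drop = FALSE] * 0
  delta["MS", analyte] <- d * cfg0$sigma_log10[[analyte]]
  bilemarkers::cohort_config(
    group_sizes = c(NMOSD_AQP4neg = n_pos, MS = n_neg),
    baseline_log10 = cfg0$baseline_log10, sigma_log10 = cfg0$sigma_log10,
    delta = delta)
}
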