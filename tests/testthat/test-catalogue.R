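test_that("pools sum their members on simple profiles", {
  p <- setNames(rep(1, 15), ba_analytes())
  pools <- compute_pools(p)
  expect_equal(pools[["TBA"]], 15)
  expect_equal(pools[["primary"]], 6)
  expect_equal(pools[["secondary"]], 9)
  expect_equal(pools[["OH12"]], 6)
  expect_equal(pools[["non_OH12"]], 9)
  expect_equal(pools[["CAs"]], 3)
  expect_equal(pools[["neurotoxic"]], 3)

  q <- setNames(rep(0, 15), ba_analytes())
  q["CA"] <- 2
  pools <- compute_pools(q)
  expect_equal(pools[["TBA"]], 2)
  expect_equal(pools[["primary"]], 2)
  expect_equal(pools[["secondary"]], 0)
  expect_equal(pools[["unconjugated"]], 2)
  expect_equal(pools[["OH12"]], 2)
})

test_that("percent and ratio operations follow their contracts", {
  p <- setNames(rep(1, 15), ba_analytes())
  expect_equal(compute_percent(p, "primary"), 6 / 15)
  expect_equal(compute_ratio(p, "OH12", "non_OH12"), 6 / 9)

  q <- setNames(rep(0, 15), ba_analytes())
  q["CA"] <- 1
  expect_equal(compute_percent(q, "CA"), 1)

  q["GLCA"] <- 2; q["TLCA"] <- 1
  expect_equal(compute_ratio(q, "GLCA", "TLCA"), 2)
  q["TLCA"] <- 0
  expect_true(is.na(compute_ratio(q, "GLCA", "TLCA")))

  zero <- setNames(rep(0, 15), ba_analytes())
  expect_true(is.na(compute_percent(zero, "CA")))
  expect_error(compute_ratio(p, "GLCA", "no_such_pool"), "unknown")
})

test_that("profile validation names the offending analyte", {
  p <- setNames(rep(1, 15), ba_analytes())
  p["DCA"] <- -0.1
  expect_error(compute_pools(p), "DCA")
  p["DCA"] <- NaN
  expect_error(compute_pools(p), "DCA")
  expect_error(compute_pools(p[-1]), "TCA")
})

test_that("the catalogue has exactly 71 uniquely named indices of 4 kinds", {
  cat71 <- ba_catalogue()
  nm <- vapply(cat71, `[[`, character(1), "name")
  kinds <- vapply(cat71, `[[`, character(1), "kind")
  expect_length(cat71, 71)
  expect_false(anyDuplicated(nm) > 0)
  expect_equal(unname(table(kinds)[c("raw", "pool", "percent", "ratio")]),
               c(15L, 17L, 31L, 8L), ignore_attr = TRUE)
  # every index the analysis singles out is present
  expect_true(all(c("OH12_over_nonOH12", "GLCA_over_TLCA", "GDCA_over_TDCA",
                    "conjugated_UDCAs", "pct_GLCA", "DCA", "TLCA", "TDCA")
                  %in% nm))
  # all referenced names resolve
  for (def in cat71) {
    for (ref in c(def$numerator, def$denominator)) {
      expect_true(ref %in% c(ba_analytes(), names(ba_pools())), label = ref)
    }
  }
})

test_that("every catalogue value matches the brute-force oracle", {
  set.seed(42)
  for (i in 1:1000) {
    p <- random_profile()
    got <- compute_indices(p)
    want <- oracle_indices(p)
    expect_equal(got, want[names(got)], tolerance = 1e-12)
  }
})

test_that("pool partitions and scale equivariance hold on random profiles", {
  set.seed(7)
  for (i in 1:200) {
    p <- random_profile()
    pools <- compute_pools(p)
    tba <- pools[["TBA"]]
    expect_equal(pools[["primary"]] + pools[["secondary"]], tba,
                 tolerance = 1e-9)
    expect_equal(pools[["OH12"]] + pools[["non_OH12"]], tba, tolerance = 1e-9)
    expect_equal(pools[["G_conjugated"]] + pools[["T_conjugated"]] +
                   pools[["unconjugated"]], tba, tolerance = 1e-9)
    idx <- compute_indices(p)
    pct_raw <- idx[paste0("pct_", ba_analytes())]
    expect_equal(sum(pct_raw), 1, tolerance = 1e-9)
    expect_true(all(pct_raw >= 0 & pct_raw <= 1))
    # scaling concentrations leaves proportions and ratios unchanged
    idx2 <- compute_indices(p * 3.7)
    kinds <- vapply(ba_catalogue(), `[[`, character(1), "kind")
    scale_free <- kinds %in% c("percent", "ratio")
    expect_equal(idx2[scale_free], idx[scale_free], tolerance = 1e-12)
    expect_equal(idx2[!scale_free], 3.7 * idx[!scale_free], tolerance = 1e-12)
  }
})

test_that("feature tables propagate missingness and reject bad cohorts", {
  p <- setNames(rep(1, 15), ba_analytes())
  coh <- data.frame(subject_id = c("a", "b", "c"), group = "HC",
                    as.data.frame(rbind(p, p, p)))
  ft <- build_feature_table(coh)
  expect_equal(dim(ft), c(3L, 2L + 71L))
  expect_equal(attr(ft, "n_missing"), 0L)

  coh2 <- coh
  coh2$TLCA[1] <- 0
  ft2 <- build_feature_table(coh2)
  na_cols <- names(ft2)[vapply(ft2, function(col) anyNA(col), logical(1))]
  expect_equal(na_cols, "GLCA_over_TLCA")
  expect_equal(attr(ft2, "n_missing"), 1L)

  expect_error(build_feature_table(coh[, -3]), "TCA")
  coh3 <- coh; coh3$subject_id <- c("a", "a", "b")
  expect_error(build_feature_table(coh3), "duplicate")
})

test_that("catalogue JSON round-trips and evaluates identically", {
  path <- tempfile(fileext = ".json")
  write_catalogue_json(ba_catalogue(), path)
  back <- read_catalogue_json(path)
  expect_length(back, 71)
  set.seed(5)
  p <- random_profile()
  expect_equal(compute_indices(p, back), compute_indices(p))
})
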