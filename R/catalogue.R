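#' The 15 measured bile-acid analytes
#'
#' Canonical analyte order for the targeted serum panel: the six primary bile
#' acids (taurine/glycine conjugates of cholic and chenodeoxycholic acid plus
#' the free acids) followed by the nine secondary bile acids (deoxycholic,
#' lithocholic and ursodeoxycholic families). All concentrations are in
#' micromol/L.
#'
#' @return Character vector of length 15.
#' @export
ba_analytes <- function() {
  c("TCA", "TCDCA", "GCA", "GCDCA", "CDCA", "CA",
    "DCA", "GDCA", "TDCA", "LCA", "GLCA", "TLCA",
    "UDCA", "GUDCA", "TUDCA")
}

#' Bile-acid pool membership lists
#'
#' The 17 derived pools, each defined as the plain sum of its member analytes.
#' "conjugated" follows the primary-conjugates-only convention
#' (TCA + TCDCA + GCA + GCDCA); it is deliberately narrower than the chemical
#' notion of a conjugated bile acid, so that G_conjugated + T_conjugated +
#' unconjugated — not conjugated + unconjugated — partitions TBA.
#' "OH12" collects the carbon-12 hydroxylated species (cholic/deoxycholic
#' families); OH12 + non_OH12 and primary + secondary both partition TBA.
#'
#' @return Named list mapping pool name to a character vector of analytes.
#' @export
ba_pools <- function() {
  list(
    primary        = c("TCA", "TCDCA", "GCA", "GCDCA", "CDCA", "CA"),
    secondary      = c("DCA", "GDCA", "TDCA", "LCA", "GLCA", "TLCA",
                       "UDCA", "GUDCA", "TUDCA"),
    TBA            = ba_analytes(),
    conjugated     = c("TCA", "TCDCA", "GCA", "GCDCA"),
    unconjugated   = c("CA", "CDCA", "DCA", "LCA", "UDCA"),
    G_conjugated   = c("GCA", "GCDCA", "GDCA", "GLCA", "GUDCA"),
    T_conjugated   = c("TCA", "TCDCA", "TDCA", "TLCA", "TUDCA"),
    OH12           = c("CA", "TCA", "GCA", "DCA", "TDCA", "GDCA"),
    non_OH12       = c("CDCA", "TCDCA", "GCDCA", "LCA", "TLCA", "GLCA",
                       "UDCA", "GUDCA", "TUDCA"),
    CAs            = c("GCA", "TCA", "CA"),
    CDCAs          = c("GCDCA", "TCDCA", "CDCA"),
    DCAs           = c("GDCA", "TDCA", "DCA"),
    LCAs           = c("GLCA", "TLCA", "LCA"),
    UDCAs          = c("GUDCA", "TUDCA", "UDCA"),
    neurotoxic     = c("GCA", "GCDCA", "GDCA"),
    neuroprotective = c("GUDCA", "TUDCA", "UDCA"),
    conjugated_UDCAs = c("GUDCA", "TUDCA")
  )
}

# validate a single profile: named numeric covering exactly the 15 analytes,
# finite and non-negative; errors name the offending analyte
validate_profile <- function(profile) {
  analytes <- ba_analytes()
  if (is.null(names(profile))) {
    stop("profile must be a named numeric vector of analyte concentrations")
  }
  missing <- setdiff(analytes, names(profile))
  if (length(missing) > 0) {
    stop("profile is missing analyte(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(profile), analytes)
  if (length(extra) > 0) {
    stop("profile has unknown analyte(s): ", paste(extra, collapse = ", "))
  }
  profile <- profile[analytes]
  bad <- !is.finite(profile) | profile < 0
  if (any(bad)) {
    stop("non-finite or negative concentration for analyte(s): ",
         paste(analytes[bad], collapse = ", "))
  }
  profile
}

#' Compute the 17 bile-acid pools for one subject
#'
#' Each pool is the exact arithmetic sum of its member analyte concentrations
#' (see [ba_pools()]); units are micromol/L.
#'
#' @param profile Named numeric vector with one non-negative, finite
#'   concentration per analyte of [ba_analytes()].
#' @return Named numeric vector of the 17 pool values.
#' @export
#' @examples
#' p <- setNames(rep(1, 15), ba_analytes())
#' compute_pools(p)[c("TBA", "primary", "secondary")]
compute_pools <- function(profile) {
  profile <- validate_profile(profile)
  vapply(ba_pools(), function(members) sum(profile[members]), numeric(1))
}

# resolve a pool-or-analyte name to its value for one profile
resolve_value <- function(profile, name) {
  if (name %in% names(profile)) return(unname(profile[name]))
  pools <- ba_pools()
  if (name %in% names(pools)) return(sum(profile[pools[[name]]]))
  stop("unknown analyte or pool name: ", name)
}

#' Proportion of an index within the total bile-acid pool
#'
#' @param profile Named numeric analyte vector (see [compute_pools()]).
#' @param index_name An analyte or pool name.
#' @return `value / TBA` as a fraction in \[0, 1\], or `NA` when TBA is zero
#'   (never an error: a fully depleted pool is a missing proportion).
#' @export
compute_percent <- function(profile, index_name) {
  profile <- validate_profile(profile)
  tba <- sum(profile)
  if (tba == 0) return(NA_real_)
  resolve_value(profile, index_name) / tba
}

#' Ratio of two bile-acid indices
#'
#' @param profile Named numeric analyte vector.
#' @param num,den Analyte or pool names for numerator and denominator.
#' @return `num / den`, or `NA` when the denominator is zero (never infinity).
#' @export
compute_ratio <- function(profile, num, den) {
  profile <- validate_profile(profile)
  d <- resolve_value(profile, den)
  if (d == 0) return(NA_real_)
  resolve_value(profile, num) / d
}

#' The frozen 71-index catalogue
#'
#' The fixed, ordered set of derived indices computed from the 15-analyte
#' panel: 15 raw concentrations, 17 pools, 15 analyte proportions, 16 pool
#' proportions (every pool except TBA itself) and 8 ratios. Proportions are
#' stored as fractions in \[0, 1\]; rendering as percentages is left to
#' presentation code.
#'
#' @return An object of class `ba_catalogue`: a list of index definitions,
#'   each with `name`, `kind` (`raw`, `pool`, `percent` or `ratio`),
#'   `numerator` and `denominator` fields.
#' @export
ba_catalogue <- function() {
  analytes <- ba_analytes()
  pools <- ba_pools()
  defs <- list()
  for (a in analytes) {
    defs[[length(defs) + 1L]] <- list(name = a, kind = "raw",
                                      numerator = a, denominator = character(0))
  }
  for (p in names(pools)) {
    defs[[length(defs) + 1L]] <- list(name = p, kind = "pool",
                                      numerator = pools[[p]],
                                      denominator = character(0))
  }
  for (a in analytes) {
    defs[[length(defs) + 1L]] <- list(name = paste0("pct_", a), kind = "percent",
                                      numerator = a, denominator = "TBA")
  }
  for (p in setdiff(names(pools), "TBA")) {
    defs[[length(defs) + 1L]] <- list(name = paste0("pct_", p), kind = "percent",
                                      numerator = p, denominator = "TBA")
  }
  ratios <- list(
    OH12_over_nonOH12 = c("OH12", "non_OH12"),
    GLCA_over_TLCA    = c("GLCA", "TLCA"),
    GDCA_over_TDCA    = c("GDCA", "TDCA"),
    primary_over_secondary = c("primary", "secondary"),
    conjugated_over_unconjugated = c("conjugated", "unconjugated"),
    Gconj_over_Tconj  = c("G_conjugated", "T_conjugated"),
    neurotoxic_over_neuroprotective = c("neurotoxic", "neuroprotective"),
    CAs_over_CDCAs    = c("CAs", "CDCAs")
  )
  for (r in names(ratios)) {
    defs[[length(defs) + 1L]] <- list(name = r, kind = "ratio",
                                      numerator = ratios[[r]][1],
                                      denominator = ratios[[r]][2])
  }
  structure(defs, class = "ba_catalogue")
}

#' @export
print.ba_catalogue <- function(x, ...) {
  kinds <- vapply(x, `[[`, character(1), "kind")
  cat("Bile-acid index catalogue:", length(x), "indices\n")
  print(table(factor(kinds, levels = c("raw", "pool", "percent", "ratio"))))
  invisible(x)
}

#' Evaluate every catalogue index for one subject
#'
#' @param profile Named numeric analyte vector.
#' @param catalogue An index catalogue, by default [ba_catalogue()].
#' @return Named numeric vector, one value per index in catalogue order.
#'   Proportions with TBA = 0 and ratios with a zero denominator are `NA`.
#' @export
compute_indices <- function(profile, catalogue = ba_catalogue()) {
  profile <- validate_profile(profile)
  vals <- vapply(catalogue, function(def) {
    switch(def$kind,
      raw = unname(profile[def$numerator]),
      pool = sum(profile[def$numerator]),
      percent = {
        tba <- sum(profile)
        if (tba == 0) NA_real_ else resolve_value(profile, def$numerator) / tba
      },
      ratio = {
        d <- resolve_value(profile, def$denominator)
        if (d == 0) NA_real_ else resolve_value(profile, def$numerator) / d
      },
      stop("unknown index kind: ", def$kind))
  }, numeric(1))
  names(vals) <- vapply(catalogue, `[[`, character(1), "name")
  vals
}

#' Build the subjects-by-indices feature table for a cohort
#'
#' @param cohort Data frame with a `subject_id` column, a `group` column, the
#'   15 analyte columns of [ba_analytes()], and any further columns (for
#'   example `EDSS`, `lesion_segments`) carried through as covariates.
#' @param catalogue Index catalogue, by default [ba_catalogue()].
#' @return Data frame of class `ba_feature_table`: `subject_id`, `group`,
#'   covariates, then one column per catalogue index. The number of missing
#'   (NA) index cells is attached as attribute `n_missing`.
#' @export
build_feature_table <- function(cohort, catalogue = ba_catalogue()) {
  stopifnot(is.data.frame(cohort))
  if (!"subject_id" %in% names(cohort)) stop("cohort must have a subject_id column")
  if (!"group" %in% names(cohort)) stop("cohort must have a group column")
  if (anyDuplicated(cohort$subject_id)) stop("duplicate subject ids in cohort")
  missing_cols <- setdiff(ba_analytes(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing analyte column(s): ", paste(missing_cols, collapse = ", "))
  }
  idx <- t(apply(as.matrix(cohort[, ba_analytes(), drop = FALSE]), 1, function(row) {
    compute_indices(stats::setNames(as.numeric(row), ba_analytes()), catalogue)
  }))
  covars <- setdiff(names(cohort), c("subject_id", "group", ba_analytes()))
  out <- cbind(cohort[, c("subject_id", "group"), drop = FALSE],
               cohort[, covars, drop = FALSE],
               as.data.frame(idx))
  rownames(out) <- NULL
  attr(out, "n_missing") <- sum(is.na(idx))
  attr(out, "index_names") <- colnames(idx)
  class(out) <- c("ba_feature_table", class(out))
  out
}

#' Export or import an index catalogue as JSON
#'
#' @param catalogue A `ba_catalogue` object.
#' @param path File path.
#' @return `read_catalogue_json()` returns a `ba_catalogue`.
#' @export
write_catalogue_json <- function(catalogue, path) {
  jsonlite::write_json(unclass(catalogue), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_catalogue_json
#' @export
read_catalogue_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  defs <- lapply(raw, function(d) {
    list(name = d$name, kind = d$kind,
         numerator = as.character(unlist(d$numerator)),
         denominator = as.character(unlist(d$denominator)))
  })
  structure(defs, class = "ba_catalogue")
}
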