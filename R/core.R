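#' Emission-factor accounting: activity x emission factor
#'
#' The inventory engine: an annual emission for one source in one province is
#' the activity datum multiplied by its emission factor,
#' `E(y) = sum_i sum_j AD_ij(y) * EF_i`, carried out per category and summed
#' later by [aggregate_emissions()]. Units are composed explicitly: the EF
#' denominator must match the activity unit's substance (N, product, dm,
#' TJ, ...), and the result is converted to the internal mass basis,
#' Gg N2O-N per year.
#'
#' @param ad_value Activity amount(s), non-negative; vectorized.
#' @param ad_unit Activity unit, e.g. `"Gg N"`, `"kt product"`, `"TJ"`.
#' @param ef_value Emission factor value(s), non-negative.
#' @param ef_unit EF unit, `"<emitted>/<activity>"`, e.g. `"kg N2O-N/kg N"`,
#'   `"t N2O/t product"`, `"kg N2O/TJ"`.
#' @return Emission in Gg N2O-N per year (numeric, same length as inputs).
#' @examples
#' emission(100, "Gg N", 0.01, "kg N2O-N/kg N") # 1.0
#' emission(500, "kt product", 0.3, "t N2O/t product") # 95.45... Gg N2O-N
#' @export
emission <- function(ad_value, ad_unit, ef_value, ef_unit) {
  if (any(ad_value < 0, na.rm = TRUE)) {
    abort("Activity data must be non-negative.", class = "n2o_domain_error")
  }
  if (any(ef_value < 0, na.rm = TRUE)) {
    abort("Emission factors must be non-negative.", class = "n2o_domain_error")
  }
  ad <- parse_amount_unit(ad_unit)
  ef <- parse_ef_unit(ef_unit)
  if (!identical(ad$substance, ef$den$substance)) {
    abort(paste0(
      "Unit mismatch: activity unit '", ad_unit,
      "' does not compose with EF unit '", ef_unit,
      "' (activity substance '", ad$substance,
      "' vs EF denominator '", ef$den$substance, "')."
    ), class = "n2o_unit_error")
  }
  # activity expressed in the EF's denominator units, then emitted mass in Gg
  ad_in_den <- ad_value * ad$scale / ef$den$scale
  gas_gg <- ad_in_den * ef_value * ef$num$scale
  if (ef$num$substance == "N2O") gas_gg <- n2o_to_n2o_n(gas_gg)
  gas_gg
}

#' Look up a stratified emission factor
#'
#' EF tables are long tibbles with columns `category`, `stratum`
#' (semicolon-joined `key=value` pairs, `""` for unstratified), `value`,
#' `unit` and optional `low`, `high`, `distribution`. Lookup requires an
#' exact match on category and on the full stratum key set.
#'
#' @param efs EF tibble.
#' @param category Category id.
#' @param strata Named character vector of stratum keys, e.g.
#'   `c(climate_region = "East", land_type = "upland")`.
#' @return The matching EF row (one-row tibble).
#' @export
ef_lookup <- function(efs, category, strata = character()) {
  key <- ef_stratum_key(strata)
  hit <- efs[efs$category == category & ef_normalize_key(efs$stratum) == key, ]
  if (nrow(hit) == 0L) {
    abort(paste0(
      "No EF registered for category '", category, "' with strata {",
      key, "}. Available strata for this category: ",
      paste(unique(efs$stratum[efs$category == category]), collapse = " | ")
    ), class = "n2o_lookup_error")
  }
  if (nrow(hit) > 1L) {
    abort(paste0("Ambiguous EF lookup for '", category, "' {", key, "}."),
          class = "n2o_lookup_error")
  }
  hit
}

#' @keywords internal
ef_stratum_key <- function(strata) {
  if (length(strata) == 0) return("")
  ord <- order(names(strata))
  paste(paste0(names(strata)[ord], "=", unname(strata)[ord]), collapse = ";")
}

#' @keywords internal
ef_normalize_key <- function(keys) {
  vapply(keys, function(k) {
    if (is.na(k) || k == "") return("")
    parts <- strsplit(k, ";", fixed = TRUE)[[1]]
    paste(sort(trimws(parts)), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Build an emission-estimate tibble
#'
#' The inventory's long record: one row per year/province/sector/category
#' with the mass on the internal N2O-N basis and an optional 95% interval.
#'
#' @param year,province,sector,category Identifiers (vectorized).
#' @param n2o_n_gg Emission in Gg N2O-N per year, non-negative.
#' @param ci_low,ci_high Optional interval bounds (Gg N2O-N).
#' @param substituted Logical gap-fill provenance flag.
#' @return A tibble of class-free long records.
#' @export
emission_estimate <- function(year, province, sector, category, n2o_n_gg,
                              ci_low = NA_real_, ci_high = NA_real_,
                              substituted = FALSE) {
  if (any(n2o_n_gg < 0, na.rm = TRUE)) {
    abort("Emission mass must be non-negative.", class = "n2o_domain_error")
  }
  ok <- !is.na(ci_low) & !is.na(ci_high)
  if (any(ok & (ci_low > n2o_n_gg | n2o_n_gg > ci_high))) {
    abort("Interval must bracket the estimate (low <= mass <= high).",
          class = "n2o_domain_error")
  }
  tibble(year = as.integer(year), province = province, sector = sector,
         category = category, n2o_n_gg = n2o_n_gg,
         ci_low = ci_low, ci_high = ci_high, substituted = substituted)
}

#' Fill missing years from the nearest populated year
#'
#' Inventory practice when a sector's statistics start late or end early:
#' a missing year takes the value of the nearest populated year, ties broken
#' toward the later year, and the substitution is flagged in the output so
#' downstream reports can mark borrowed values.
#'
#' @param series Named numeric vector (names are years) or a two-column
#'   data frame `(year, value)`.
#' @param years Integer vector of years the output must cover. Defaults to
#'   `min:max` of the populated years.
#' @return Tibble with columns `year`, `value`, `substituted`.
#' @examples
#' gap_fill(c(`1985` = 46.5, `1995` = 94.6), years = 1980:1995)
#' @export
gap_fill <- function(series, years = NULL) {
  if (is.data.frame(series)) {
    have_years <- as.integer(series[[1]])
    values <- as.numeric(series[[2]])
  } else {
    have_years <- as.integer(names(series))
    values <- as.numeric(series)
  }
  keep <- !is.na(values)
  have_years <- have_years[keep]
  values <- values[keep]
  if (length(values) == 0L) {
    abort("Cannot gap-fill an empty series.", class = "n2o_domain_error")
  }
  if (is.null(years)) years <- seq(min(have_years), max(have_years))
  years <- as.integer(years)
  idx <- vapply(years, function(y) {
    d <- abs(have_years - y)
    cand <- which(d == min(d))
    # tie toward the later year
    cand[which.max(have_years[cand])]
  }, integer(1))
  tibble(year = years, value = values[idx],
         substituted = !(years %in% have_years))
}

#' Aggregate emission estimates
#'
#' Sums an emission-estimate table over any subset of
#' `year, province, region, sector, category`. Sums are exact over the
#' collection; totals are reported in Gg N2O (mass basis converted with
#' 44/28) alongside the internal N2O-N sum. Grouping by `region` joins the
#' province-to-region registry.
#'
#' @param estimates Emission-estimate tibble (see [emission_estimate()]).
#' @param by Character vector of grouping keys (may be empty for a grand
#'   total).
#' @param registry Region registry tibble, used only when `"region"` is in
#'   `by`. Defaults to [region_registry()].
#' @return Tibble with the grouping columns plus `n2o_n_gg` and `n2o_gg`.
#'   An empty input with no grouping yields a single zero row.
#' @export
aggregate_emissions <- function(estimates, by = c("year", "sector"),
                                registry = NULL) {
  allowed <- c("year", "province", "region", "sector", "category")
  bad <- setdiff(by, allowed)
  if (length(bad) > 0) {
    abort(paste0("Unknown grouping key(s): ", paste(bad, collapse = ", ")),
          class = "n2o_lookup_error")
  }
  est <- estimates
  if ("region" %in% by) {
    if (is.null(registry)) registry <- region_registry()
    est <- dplyr::left_join(est, registry[c("province", "region")],
                            by = "province")
  }
  if (nrow(est) == 0L) {
    if (length(by) == 0L) return(tibble(n2o_n_gg = 0, n2o_gg = 0))
    out <- tibble()
    for (k in by) out[[k]] <- if (k == "year") integer() else character()
    out$n2o_n_gg <- numeric()
    out$n2o_gg <- numeric()
    return(out)
  }
  out <- est |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n2o_n_gg = sum(.data$n2o_n_gg), .groups = "drop")
  out$n2o_gg <- n2o_n_to_n2o(out$n2o_n_gg)
  out
}

#' Read an activity-data CSV
#'
#' Expected columns: `year, province, sector, category, variable, value,
#' unit` (UTF-8 with header). Values must be non-negative.
#' @param path CSV path.
#' @return Tibble of activity records.
#' @export
read_activity_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("year", "province", "sector", "category", "variable",
                "value", "unit")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    abort(paste0("activity.csv is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "n2o_config_error")
  }
  if (any(x$value < 0, na.rm = TRUE)) {
    abort("Activity values must be non-negative.", class = "n2o_domain_error")
  }
  x$year <- as.integer(x$year)
  x
}

#' Read an emission-factor CSV
#'
#' Expected columns: `category, stratum, value, unit, low, high,
#' distribution` with `stratum` as semicolon-joined `key=value` pairs.
#' @param path CSV path.
#' @return Tibble of EF rows.
#' @export
read_ef_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("category", "stratum", "value", "unit")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    abort(paste0("ef.csv is missing column(s): ", paste(miss, collapse = ", ")),
          class = "n2o_config_error")
  }
  x$stratum[is.na(x$stratum)] <- ""
  bad <- !is.na(x$value) & x$value < 0
  if (any(bad)) abort("EF values must be non-negative.",
                      class = "n2o_domain_error")
  if (all(c("low", "high") %in% names(x))) {
    ok <- !is.na(x$low) & !is.na(x$high)
    if (any(ok & (x$low > x$value | x$value > x$high))) {
      abort("EF bounds must satisfy low <= value <= high.",
            class = "n2o_domain_error")
    }
  }
  x
}
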