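#' @keywords internal
as_series <- function(series) {
  if (is.data.frame(series)) {
    out <- tibble(year = as.integer(series[[1]]),
                  value = as.numeric(series[[2]]))
  } else {
    out <- tibble(year = as.integer(names(series)),
                  value = as.numeric(series))
  }
  if (any(diff(out$year) <= 0)) out <- out[order(out$year), ]
  if (anyDuplicated(out$year)) {
    abort("Series years must be unique.", class = "n2o_domain_error")
  }
  out
}

#' Endpoint percent change between two years
#'
#' Decadal rates are endpoint ratios, `100 * (v(y1) - v(y0)) / v(y0)`,
#' not regression-based.
#'
#' @param series Annual series (named vector or `(year, value)` frame).
#' @param y0,y1 Start and end years (must be present).
#' @return Percent change (full precision; report rounded to one decimal).
#' @examples
#' decadal_change_pct(c(`1980` = 889.6, `1990` = 1229.8), 1980, 1990)
#' @export
decadal_change_pct <- function(series, y0, y1) {
  s <- as_series(series)
  v0 <- s$value[s$year == y0]
  v1 <- s$value[s$year == y1]
  if (length(v0) != 1L || length(v1) != 1L) {
    abort("Both years must be present in the series.",
          class = "n2o_lookup_error")
  }
  if (v0 == 0) {
    abort("Percent change from a zero baseline is undefined.",
          class = "n2o_domain_error")
  }
  100 * (v1 - v0) / v0
}

#' Component contribution to a total's change
#'
#' Returns both conventions used in decadal reporting: the component's
#' change relative to the total's baseline,
#' `100 * (comp(y1) - comp(y0)) / total(y0)`, and its share of the total
#' increase, `100 * dcomp / dtotal`.
#'
#' @param component,total Annual series.
#' @param y0,y1 Window endpoints.
#' @return List with `contribution_pct` and `share_of_increase_pct`
#'   (the share is `NA` with a warning when the total did not change).
#' @export
contribution_pct <- function(component, total, y0, y1) {
  comp <- as_series(component)
  tot <- as_series(total)
  c0 <- comp$value[comp$year == y0]; c1 <- comp$value[comp$year == y1]
  t0 <- tot$value[tot$year == y0];   t1 <- tot$value[tot$year == y1]
  if (length(c0) != 1L || length(c1) != 1L ||
      length(t0) != 1L || length(t1) != 1L) {
    abort("Both years must be present in both series.",
          class = "n2o_lookup_error")
  }
  if (t0 == 0) {
    abort("Contribution against a zero baseline is undefined.",
          class = "n2o_domain_error")
  }
  dt <- t1 - t0
  share <- if (dt == 0) {
    warn("Total change is zero; share of increase undefined.")
    NA_real_
  } else {
    100 * (c1 - c0) / dt
  }
  list(contribution_pct = 100 * (c1 - c0) / t0,
       share_of_increase_pct = share)
}

#' Sector shares of emissions in a year
#'
#' @param table Aggregated inventory tibble with `year`, `sector`,
#'   `n2o_gg` (e.g. from [aggregate_emissions()]).
#' @param year Reporting year.
#' @param basis `"anthropogenic"` (excludes the natural sector from both
#'   numerator set and denominator) or `"total"`.
#' @return Tibble `sector`, `n2o_gg`, `share_pct`; shares sum to 100
#'   within rounding.
#' @export
sector_share <- function(table, year, basis = c("anthropogenic", "total")) {
  basis <- match.arg(basis)
  t_y <- table[table$year == year, ]
  if (basis == "anthropogenic") t_y <- t_y[t_y$sector != "natural", ]
  expected <- setdiff(fan_sectors(), if (basis == "anthropogenic") "natural"
                      else character())
  missing_sectors <- setdiff(intersect(expected, unique(table$sector)),
                             unique(t_y$sector))
  if (nrow(t_y) == 0L) {
    abort(paste0("No sector totals for year ", year, "."),
          class = "n2o_lookup_error")
  }
  if (length(missing_sectors) > 0) {
    abort(paste0("Missing sector(s) for year ", year, ": ",
                 paste(missing_sectors, collapse = ", ")),
          class = "n2o_lookup_error")
  }
  t_y <- t_y |>
    dplyr::group_by(.data$sector) |>
    dplyr::summarise(n2o_gg = sum(.data$n2o_gg), .groups = "drop")
  t_y$share_pct <- 100 * t_y$n2o_gg / sum(t_y$n2o_gg)
  t_y
}

#' Ordinary least-squares trend and accumulated change
#'
#' OLS slope of value on year; the accumulated change multiplies the slope
#' by the window length in years (41 for a 1980-2020 inventory window, the
#' reporting convention even though the window spans 40 intervals).
#'
#' @param series Annual series (at least 3 points).
#' @param years_multiplier Multiplier for the accumulated change
#'   (default 41).
#' @return List with `slope_gg_yr` and `accumulated_gg`.
#' @export
linear_trend <- function(series, years_multiplier = 41) {
  s <- as_series(series)
  if (nrow(s) < 3L) {
    abort("Linear trend needs at least 3 points.", class = "n2o_domain_error")
  }
  slope <- unname(stats::coef(stats::lm(value ~ year, data = s))["year"])
  list(slope_gg_yr = slope, accumulated_gg = slope * years_multiplier)
}

#' Mann-Kendall monotonic trend test
#'
#' The S statistic counts the signs of all pairwise differences; the
#' variance uses the tie correction
#' `[n(n-1)(2n+5) - sum t(t-1)(2t+5)] / 18`, and the p-value comes from the
#' continuity-corrected normal approximation (two-sided). No pre-whitening
#' is applied. An all-identical series returns `tau = 0`, `p = 1`.
#'
#' @param series Annual series (at least 4 points).
#' @param alpha Significance level for the trend flag.
#' @return List with `s`, `tau`, `var_s`, `z`, `p`, and
#'   `increasing` (TRUE when `p < alpha` and `S > 0`).
#' @export
mann_kendall <- function(series, alpha = 0.05) {
  s <- as_series(series)
  x <- s$value
  n <- length(x)
  if (n < 4L) {
    abort("Mann-Kendall needs at least 4 points.", class = "n2o_domain_error")
  }
  d <- sign(outer(x, x, "-"))
  S <- sum(d[lower.tri(d)])
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  tau <- S / (n * (n - 1) / 2)
  if (var_s == 0) {
    z <- 0
    p <- 1
  } else {
    z <- (S - sign(S)) / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(s = S, tau = tau, var_s = var_s, z = z, p = p,
       increasing = (p < alpha) && (S > 0))
}

#' Export the full inventory (FAN layout)
#'
#' Writes `fan_inventory.csv` (province-level anthropogenic categories:
#' `year, province, region, sector, category, n2o_gg, ci_low, ci_high,
#' substituted_flag`) and, when a gridded natural result is supplied,
#' `fan_natural.csv` (long `cell_id, x, y, landcover, year, flux_gn_m2`
#' annual 25-km grid, flux in g N2O-N per m^2 per year). Doubles are
#' written at full round-trip precision so re-reading reproduces the table
#' bit-for-bit.
#'
#' @param table Emission-estimate tibble.
#' @param dir Output directory (created if needed).
#' @param natural Optional `cells` tibble from [simulate_grid()] joined to
#'   its grid (columns `cell_id`, `x`, `y`, `landcover`, `year`,
#'   `flux_gn_m2`).
#' @param registry Region registry for the region column.
#' @return Invisibly, the paths written.
#' @export
export_fan <- function(table, dir, natural = NULL, registry = NULL) {
  if (is.null(registry)) registry <- region_registry()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inv <- table
  if (!"region" %in% names(inv)) {
    inv <- dplyr::left_join(inv, registry[c("province", "region")],
                            by = "province")
  }
  for (col in c("ci_low", "ci_high")) {
    if (!col %in% names(inv)) inv[[col]] <- NA_real_
  }
  if (!"substituted" %in% names(inv)) inv$substituted <- FALSE
  out <- tibble(
    year = inv$year, province = inv$province, region = inv$region,
    sector = inv$sector, category = inv$category,
    n2o_gg = fmt_roundtrip(n2o_n_to_n2o(inv$n2o_n_gg)),
    ci_low = fmt_roundtrip(ifelse(is.na(inv$ci_low), NA_real_,
                                  n2o_n_to_n2o(inv$ci_low))),
    ci_high = fmt_roundtrip(ifelse(is.na(inv$ci_high), NA_real_,
                                   n2o_n_to_n2o(inv$ci_high))),
    substituted_flag = inv$substituted
  )
  inv_path <- file.path(dir, "fan_inventory.csv")
  tryCatch(readr::write_csv(out, inv_path, na = ""),
           error = function(e) abort(paste0("Failed writing ", inv_path, ": ",
                                            conditionMessage(e))))
  paths <- inv_path
  if (!is.null(natural)) {
    nat_path <- file.path(dir, "fan_natural.csv")
    keep <- intersect(c("cell_id", "x", "y", "landcover", "year",
                        "flux_gn_m2"), names(natural))
    nat <- natural[keep]
    for (col in intersect(c("x", "y", "flux_gn_m2"), names(nat))) {
      nat[[col]] <- fmt_roundtrip(nat[[col]])
    }
    tryCatch(readr::write_csv(nat, nat_path, na = ""),
             error = function(e) abort(paste0("Failed writing ", nat_path,
                                              ": ", conditionMessage(e))))
    paths <- c(paths, nat_path)
  }
  invisible(paths)
}

# shortest decimal representation that parses back to the identical double
#' @keywords internal
fmt_roundtrip <- function(x) {
  s <- rep(NA_character_, length(x))
  ok <- which(!is.na(x))
  s[ok] <- sprintf("%.15g", x[ok])
  widen <- ok[as.numeric(s[ok]) != x[ok]]
  s[widen] <- sprintf("%.17g", x[widen])
  s
}

#' Read a FAN inventory export back
#'
#' @param dir Directory holding `fan_inventory.csv` (and optionally
#'   `fan_natural.csv`).
#' @return List with `inventory` and, when present, `natural` tibbles.
#' @export
read_fan <- function(dir) {
  # base-R CSV reading: strtod parses the full-precision decimals written
  # by export_fan back to the identical doubles
  inv <- as_tibble(utils::read.csv(file.path(dir, "fan_inventory.csv"),
                                   colClasses = c(
                                     year = "integer", province = "character",
                                     region = "character",
                                     sector = "character",
                                     category = "character",
                                     n2o_gg = "numeric", ci_low = "numeric",
                                     ci_high = "numeric",
                                     substituted_flag = "logical")))
  out <- list(inventory = inv)
  nat_path <- file.path(dir, "fan_natural.csv")
  if (file.exists(nat_path)) {
    out$natural <- as_tibble(utils::read.csv(nat_path))
  }
  out
}
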