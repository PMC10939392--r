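# Independent spreadsheet-style oracles, deliberately written as plain
# kg-based arithmetic so they share no code with the package's unit engine.

# every recognized amount unit expressed in kg (count units are their own
# base)
.oracle_kg <- c("g" = 1e-3, "kg" = 1, "t" = 1e3, "Mg" = 1e3, "kt" = 1e6,
                "Gg" = 1e6, "Tg" = 1e9)

oracle_emission <- function(ad_value, ad_unit, ef_value, ef_unit) {
  split_unit <- function(u) {
    u <- trimws(u)
    if (u %in% c("TJ", "person", "head")) return(list(kg = 1, what = u))
    p <- strsplit(u, " ")[[1]]
    list(kg = .oracle_kg[[p[1]]], what = p[2])
  }
  sides <- strsplit(ef_unit, "/", fixed = TRUE)[[1]]
  num <- split_unit(sides[1])
  den <- split_unit(sides[2])
  ad <- split_unit(ad_unit)
  stopifnot(ad$what == den$what)
  emitted_kg <- (ad_value * ad$kg / den$kg) * ef_value * num$kg
  if (num$what == "N2O") emitted_kg <- emitted_kg * 28 / 44
  emitted_kg / 1e6 # kg -> Gg
}

# brute-force Mann-Kendall S over all pairs
oracle_mk_s <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) s <- s + sign(x[j] - x[i])
  }
  s
}

# closed-form OLS slope
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# printed five-snapshot sector subtotals (Gg N2O), used as inputs for
# aggregation checks
printed_subtotals <- function() {
  tibble::tribble(
    ~sector, ~year, ~n2o_gg,
    "natural", 1980L, 317.3, "natural", 1990L, 367.2, "natural", 2000L, 366.0,
    "natural", 2010L, 367.7, "natural", 2020L, 376.2,
    "energy", 1980L, 46.5, "energy", 1990L, 94.6, "energy", 2000L, 103.4,
    "energy", 2010L, 274.8, "energy", 2020L, 336.6,
    "industry", 2000L, 45.1, "industry", 2010L, 168.1, "industry", 2020L, 506.7,
    "agriculture", 1980L, 481.5, "agriculture", 1990L, 708.4,
    "agriculture", 2000L, 818.1, "agriculture", 2010L, 950.1,
    "agriculture", 2020L, 946.6,
    "waste", 1980L, 44.2, "waste", 1990L, 59.5, "waste", 2000L, 85.5,
    "waste", 2010L, 104.0, "waste", 2020L, 128.9
  )
}

printed_totals <- function() {
  tibble::tribble(
    ~year, ~anthropogenic, ~total,
    1980L, 572.2, 889.6,
    1990L, 862.6, 1229.8,
    2000L, 1052.1, 1418.0,
    2010L, 1497.1, 1864.8,
    2020L, 1918.8, 2295.0
  )
}

subtotal_estimates <- function() {
  s <- printed_subtotals()
  n2obudget::emission_estimate(
    year = s$year, province = "national", sector = s$sector,
    category = s$sector, n2o_n_gg = n2obudget::n2o_to_n2o_n(s$n2o_gg)
  )
}

# one-cell forcing table for soil-model tests
constant_forcing <- function(n_years, temp = 10, wfps = 0.6, ndep = 1,
                             co2 = 340, years = NULL) {
  if (is.null(years)) years <- seq(1980, length.out = n_years)
  tibble::tibble(year = years, temp = temp, wfps = wfps, ndep = ndep,
                 co2 = co2)
}
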