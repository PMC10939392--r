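#' Scenario configuration for the synthetic activity generator
#'
#' The generator emulates the statistical shape of four decades of Chinese
#' provincial activity data: national fertilizer N use rises about
#' threefold from 1980, peaks in 2016 at 35.4 Tg N and declines to 30.6 Tg
#' N by 2020 (the two printed national anchors, matched exactly by
#' rescaling); adipic-acid production grows steeply after 2005; coal-driven
#' energy use grows fastest in the 2000s; population growth decelerates
#' from about 15.5 to about 7.5 million persons per year. Everything else
#' is shape-only with seeded multiplicative lognormal province-level noise.
#'
#' @param seed Integer seed; a fixed seed makes every table reproducible.
#' @param n_provinces Number of provinces (default all 31).
#' @param noise_cv Province-level lognormal noise CV.
#' @return Config list.
#' @export
synth_config <- function(seed = 20200L, n_provinces = 31L, noise_cv = 0.08) {
  if (n_provinces < 1 || n_provinces > 31) {
    abort("n_provinces must be between 1 and 31.", class = "n2o_domain_error")
  }
  list(seed = as.integer(seed), n_provinces = as.integer(n_provinces),
       noise_cv = noise_cv, years = 1980:2020,
       fert_anchor = c(`2016` = 35400, `2020` = 30600)) # Gg N
}

#' @keywords internal
province_weights <- function(provinces, alpha = 3) {
  g <- stats::rgamma(length(provinces), shape = alpha)
  stats::setNames(g / sum(g), provinces)
}

#' @keywords internal
split_national <- function(national, years, provinces, weights, cv) {
  # lognormal noise per province-year, renormalized so national anchors hold
  n <- length(provinces)
  out <- lapply(seq_along(years), function(i) {
    eps <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    } else rep(1, n)
    w <- weights * eps
    w <- w / sum(w)
    tibble(year = years[i], province = provinces,
           value = national[i] * w)
  })
  dplyr::bind_rows(out)
}

#' Generate the synthetic activity-data bundle
#'
#' @param config [synth_config()] list.
#' @param registry Region registry (provinces taken from it).
#' @return List of tibbles: `fertilizer` (province fertilizer N, Gg),
#'   `n_inputs` (per land type: `f_sn`, `f_cr`, `f_som`, `f_dep`, and the
#'   leached fraction), `livestock`, `pasture_fert`, `fuels`, `plants`,
#'   `waste`, plus the `national_fertilizer` series used for calibration.
#' @export
generate_activity <- function(config = synth_config(), registry = NULL) {
  if (is.null(registry)) registry <- region_registry()
  set.seed(config$seed)
  years <- config$years
  provinces <- registry$province[seq_len(config$n_provinces)]
  ny <- length(years)

  # --- national fertilizer N (Gg N), calibrated to the two anchors -------
  peak <- config$fert_anchor[["2016"]]
  final <- config$fert_anchor[["2020"]]
  start <- peak / 3
  rise <- (1 - cos(pi * (pmin(years, 2016) - 1980) / 36)) / 2
  nat_fert <- start + (peak - start) * rise
  post <- years > 2016
  nat_fert[post] <- peak + (final - peak) * (years[post] - 2016) / 4
  w_fert <- province_weights(provinces)
  fert <- split_national(nat_fert, years, provinces, w_fert, config$noise_cv)

  # --- cropland N-input bundle ------------------------------------------
  # upland/paddy split of applied N; residue, mineralization and deposited
  # N scale with the fertilizer era but with their own shapes
  frac_upland <- 0.62
  resid_nat <- 9000 * (0.5 + 0.5 * (years - 1980) / 40)        # Gg N
  som_nat <- 7000 * (0.8 + 0.4 * (years - 1980) / 40)          # Gg N
  dep_rise <- pmin((years - 1980) / 20, 1)                     # plateau 2000
  dep_nat <- 2500 * (0.5 + 0.8 * dep_rise)                     # Gg N
  mk <- function(nat) split_national(nat, years, provinces, w_fert,
                                     config$noise_cv)
  resid <- mk(resid_nat); som <- mk(som_nat); dep <- mk(dep_nat)
  n_inputs <- dplyr::bind_rows(
    dplyr::mutate(fert, land_type = "upland", f_sn = .data$value * frac_upland),
    dplyr::mutate(fert, land_type = "paddy",
                  f_sn = .data$value * (1 - frac_upland))
  ) |>
    dplyr::select("year", "province", "land_type", "f_sn") |>
    dplyr::left_join(dplyr::rename(resid, f_cr = "value"),
                     by = c("year", "province")) |>
    dplyr::left_join(dplyr::rename(som, f_som = "value"),
                     by = c("year", "province")) |>
    dplyr::left_join(dplyr::rename(dep, f_dep = "value"),
                     by = c("year", "province"))
  share <- ifelse(n_inputs$land_type == "upland", frac_upland,
                  1 - frac_upland)
  n_inputs$f_cr <- n_inputs$f_cr * share
  n_inputs$f_som <- n_inputs$f_som * share
  n_inputs$f_dep <- n_inputs$f_dep * share
  n_inputs$frac_leach <- ifelse(n_inputs$land_type == "paddy", 0.05, 0.04)

  # --- livestock ---------------------------------------------------------
  species <- tibble(
    species = c("cattle", "swine", "poultry", "goat", "sheep"),
    base_million = c(70, 300, 3000, 100, 110),
    growth = c(0.004, 0.010, 0.018, 0.008, 0.008),
    mass_kg = c(400, 80, 1.5, 40, 45),
    excretion_rate = c(0.35, 0.50, 0.82, 0.34, 0.32),
    frac_pasture = c(0.35, 0.05, 0.02, 0.55, 0.55),
    frac_applied = c(0.35, 0.45, 0.48, 0.25, 0.25),
    frac_mms_solid = c(0.20, 0.30, 0.30, 0.15, 0.15),
    frac_mms_liquid = c(0.10, 0.20, 0.20, 0.05, 0.05)
  )
  w_lsk <- province_weights(provinces)
  livestock <- dplyr::bind_rows(lapply(seq_len(nrow(species)), function(i) {
    sp <- species[i, ]
    nat <- sp$base_million * 1e6 * exp(sp$growth * (years - 1980))
    x <- split_national(nat, years, provinces, w_lsk, config$noise_cv)
    dplyr::mutate(x, species = sp$species, headcount = .data$value,
                  mass_kg = sp$mass_kg, excretion_rate = sp$excretion_rate,
                  frac_pasture = sp$frac_pasture,
                  frac_applied = sp$frac_applied,
                  frac_mms_solid = sp$frac_mms_solid,
                  frac_mms_liquid = sp$frac_mms_liquid)[,
      c("year", "province", "species", "headcount", "mass_kg",
        "excretion_rate", "frac_pasture", "frac_applied",
        "frac_mms_solid", "frac_mms_liquid")]
  }))

  # pasture fertilization N (Gg) and residue burned (Gg dm)
  pasture_nat <- 600 * (0.4 + 0.6 * (years - 1980) / 40)
  pasture_fert <- dplyr::rename(mk(pasture_nat), n_gg = "value")
  burn_nat <- 60000 * (0.6 + 0.4 * (years - 1980) / 40)        # Gg dm
  residue_burn <- dplyr::rename(mk(burn_nat), residue_gg_dm = "value")

  # --- energy: 11 categories, activity in TJ; coal boom in the 2000s -----
  e_total <- 1.7e7 + 1.3e8 / (1 + exp(-(years - 2006) / 4))    # TJ national
  cat_share <- c(
    electricity_generation = 0.40, heat_plants = 0.035,
    petroleum_refining = 0.01, solid_fuel_manufacture = 0.02,
    other_energy_industries = 0.005, manufacturing_construction = 0.32,
    transport = 0.10, residential = 0.09,
    agriculture_forestry_fishing = 0.015, non_specified = 0.005
  )
  w_en <- province_weights(provinces)
  fuels <- dplyr::bind_rows(lapply(names(cat_share), function(cat) {
    x <- split_national(e_total * cat_share[[cat]], years, provinces, w_en,
                        config$noise_cv)
    dplyr::mutate(x, category = cat, unit = "TJ")[,
      c("year", "province", "category", "value", "unit")]
  }))
  fug_nat <- 1200 * exp(-0.08 * (years - 1980))                # kt fuel
  fugitive <- split_national(fug_nat, years, provinces, w_en,
                             config$noise_cv) |>
    dplyr::mutate(category = "fugitive_fuels", unit = "kt fuel") |>
    dplyr::select("year", "province", "category", "value", "unit")
  fuels <- dplyr::bind_rows(fuels, fugitive)

  # --- industry: adipic (steep post-2005 growth) and nitric acid ---------
  adipic_nat <- ifelse(years < 1993, 0,
                       20 * 1.05^(pmin(years, 2005) - 1993) *
                         ifelse(years > 2005, 1.22^(years - 2005), 1))
  nitric_nat <- 150 + 450 * (years - 1980) / 40
  ind_prov <- c("Henan", "Liaoning", "Shandong", "Jiangsu", "Zhejiang",
                "Hebei")
  ind_prov <- intersect(ind_prov, provinces)
  if (length(ind_prov) == 0) ind_prov <- provinces[1]
  # the two CDM-abated provinces hold small fixed shares so sector growth
  # outpaces the 2008 abatement onset
  w_fixed <- c(Henan = 0.08, Liaoning = 0.07, Shandong = 0.35,
               Jiangsu = 0.25, Zhejiang = 0.15, Hebei = 0.10)
  w_ind <- w_fixed[ind_prov]
  w_ind[is.na(w_ind)] <- 0.1
  w_ind <- w_ind / sum(w_ind)
  names(w_ind) <- ind_prov
  plants <- dplyr::bind_rows(
    dplyr::mutate(split_national(adipic_nat, years, ind_prov, w_ind,
                                 config$noise_cv), product = "adipic"),
    dplyr::mutate(split_national(nitric_nat, years, ind_prov, w_ind,
                                 config$noise_cv), product = "nitric")
  ) |>
    dplyr::rename(production_kt = "value")

  # --- waste: decelerating population, rising protein, late incineration -
  inc <- 15.5 - 8 * (years - 1980) / 40                        # million/yr
  pop_nat <- (987 + cumsum(c(0, inc[-ny]))) * 1e6
  w_pop <- province_weights(provinces)
  waste <- split_national(pop_nat, years, provinces, w_pop,
                          config$noise_cv) |>
    dplyr::rename(population = "value")
  waste$protein_kg <- 22 + 10 * (waste$year - 1980) / 40
  compost_nat <- ifelse(years < 1998, 0, 80 * 1.18^(years - 1998))
  incin_nat <- ifelse(years < 2000, 0, 100 * 1.22^(years - 2000))
  waste <- waste |>
    dplyr::left_join(dplyr::rename(split_national(compost_nat, years,
                                                  provinces, w_pop,
                                                  config$noise_cv),
                                   compost_kt = "value"),
                     by = c("year", "province")) |>
    dplyr::left_join(dplyr::rename(split_national(incin_nat, years,
                                                  provinces, w_pop,
                                                  config$noise_cv),
                                   incin_kt = "value"),
                     by = c("year", "province"))
  waste$sludge_n_gg <- 0

  list(
    national_fertilizer = tibble(year = years, fert_gg_n = nat_fert),
    fertilizer = dplyr::rename(fert, fert_gg_n = "value"),
    n_inputs = n_inputs,
    livestock = livestock,
    pasture_fert = pasture_fert,
    residue_burn = residue_burn,
    fuels = fuels,
    plants = plants,
    waste = waste
  )
}

#' Generate gridded forcings for the natural soil model
#'
#' CO2 rises monotonically from about 340 to 412 ppm; N deposition rises to
#' 2000 and then plateaus; temperature combines a cell baseline, a warming
#' trend and interannual noise; WFPS is stationary noise around a cell
#' baseline. All series are seeded and reproducible.
#'
#' @param config [synth_config()] (the seed is reused, offset so activity
#'   and forcing draws are independent).
#' @param grid Grid tibble from [make_grid()].
#' @param warming_degc_yr Linear warming trend (default 0.03 deg C / yr).
#' @return Long tibble `cell_id, year, temp, wfps, ndep, co2`.
#' @export
generate_forcings <- function(config = synth_config(), grid,
                              warming_degc_yr = 0.03) {
  set.seed(config$seed + 1L)
  years <- config$years
  ny <- length(years)
  nc <- nrow(grid)
  co2 <- 340 + 72 * ((years - 1980) / 40)^1.3
  ndep_shape <- 0.55 + 0.45 * pmin((years - 1980) / 20, 1)
  t_anom <- stats::rnorm(ny, 0, 0.25)
  base_t <- ifelse(grid$landcover == "forest",
                   stats::rnorm(nc, 9, 2.5), stats::rnorm(nc, 4, 2.5))
  base_w <- pmin(pmax(ifelse(grid$landcover == "forest",
                             stats::rnorm(nc, 0.62, 0.05),
                             stats::rnorm(nc, 0.48, 0.05)), 0.2), 0.9)
  base_nd <- pmax(ifelse(grid$landcover == "forest",
                         stats::rnorm(nc, 1.1, 0.25),
                         stats::rnorm(nc, 0.15, 0.05)), 0.03)
  out <- vector("list", ny)
  for (i in seq_len(ny)) {
    out[[i]] <- tibble(
      cell_id = grid$cell_id,
      year = years[i],
      temp = base_t + warming_degc_yr * (years[i] - 1980) + t_anom[i] +
        stats::rnorm(nc, 0, 0.15),
      wfps = pmin(pmax(base_w + stats::rnorm(nc, 0, 0.03), 0.05), 0.95),
      ndep = base_nd * ndep_shape[i] *
        pmax(stats::rnorm(nc, 1, 0.03), 0.5),
      co2 = co2[i]
    )
  }
  dplyr::bind_rows(out)
}
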