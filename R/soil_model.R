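#' Parameters of the reduced-form soil N2O model
#'
#' Annual soil nitrogen-cycle model in the hole-in-the-pipe tradition:
#' first-order substrate kinetics modulated by a Q10 temperature factor and
#' a parabolic water-filled-pore-space (WFPS) factor, with fixed N2O yield
#' fractions leaking from each microbial pathway — autotrophic
#' nitrification, heterotrophic nitrification, nitrifier denitrification
#' (both riding on the ammonium oxidation flux), and denitrifier
#' denitrification on nitrate. CO2 enters only through plant N uptake
#' (fertilization stimulates uptake, lowering soil inorganic N and hence
#' N2O).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of parameters: base rates `k_min`, `k_nit_auto`,
#'   `k_nit_het`, `k_den`, `k_up` (yr^-1 at reference conditions); `q10`
#'   and `t_ref` (deg C); `wfps_opt`, `wfps_width`; yield fractions
#'   `y_nit_auto`, `y_nit_het`, `y_nitden`, `y_denden` in `[0, 1]`;
#'   CO2-uptake sensitivity `beta` (>= 0) and `co2_ref` (ppm);
#'   `litter_frac`, the share of plant uptake returned to soil organic N.
#' @export
soil_params <- function(...) {
  p <- list(
    k_min = 0.025, k_nit_auto = 0.9, k_nit_het = 0.0045, k_den = 0.7,
    k_up = 0.5,
    q10 = 2.0, t_ref = 15,
    wfps_opt = 0.65, wfps_width = 0.6,
    y_nit_auto = 0.012, y_nit_het = 0.02, y_nitden = 0.008,
    y_denden = 0.06,
    beta = 0.35, co2_ref = 340,
    litter_frac = 0.92
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad) > 0) {
    abort(paste0("Unknown soil parameter(s): ", paste(bad, collapse = ", ")),
          class = "n2o_domain_error")
  }
  p[names(ov)] <- ov
  validate_soil_params(p)
  p
}

#' @keywords internal
validate_soil_params <- function(p) {
  yields <- c(p$y_nit_auto, p$y_nit_het, p$y_nitden, p$y_denden)
  rates <- c(p$k_min, p$k_nit_auto, p$k_nit_het, p$k_den, p$k_up)
  if (any(yields < 0 | yields > 1) || p$y_nit_auto + p$y_nitden > 1) {
    abort("Yield fractions must lie in [0,1] (and the two ammonium-flux yields must sum to <= 1).",
          class = "n2o_domain_error")
  }
  if (any(rates < 0) || p$beta < 0 || p$q10 <= 0 || p$co2_ref <= 0 ||
      p$wfps_width <= 0 || p$litter_frac < 0 || p$litter_frac > 1) {
    abort("Soil parameters out of range (rates >= 0, beta >= 0, q10 > 0).",
          class = "n2o_domain_error")
  }
  invisible(p)
}

#' Initial soil state
#'
#' @param landcover `"forest"` or `"grassland"` (vectorized).
#' @return List of pools (g N m^-2): `nh4`, `no3`, `son`, and a unitless
#'   labile-carbon index `labile_c` scaling denitrification.
#' @export
soil_init <- function(landcover) {
  forest <- landcover == "forest"
  list(
    nh4 = ifelse(forest, 0.6, 0.15),
    no3 = ifelse(forest, 0.4, 0.1),
    son = ifelse(forest, 320, 55),
    labile_c = ifelse(forest, 1.0, 0.5)
  )
}

#' One annual step of the soil N2O model
#'
#' Update order (each transformation uses first-order depletion over the
#' annual step, `pool * (1 - exp(-k * f_T * f_W))`, which keeps pools
#' non-negative by construction):
#' 1. mineralization SON -> NH4 (temperature modifier only);
#' 2. atmospheric N deposition, split equally between NH4 and NO3;
#' 3. ammonium oxidation: N2O leaks via the autotrophic-nitrification and
#'    nitrifier-denitrification yields, the remainder becomes NO3;
#' 4. heterotrophic nitrification on organic N, leaking its own yield;
#' 5. denitrification on NO3 (scaled by the labile-C index): the
#'    denitrifier-denitrification yield leaves as N2O, the rest as N2;
#' 6. plant uptake of NH4 and NO3, scaled by
#'    `1 + beta * log(CO2 / CO2_ref)`; a litter fraction returns to SON.
#' Nitrogen mass balance closes exactly each step:
#' deposition - (N2O + N2 + net uptake) = change in pools.
#'
#' All arguments are vectorized over cells.
#'
#' @param state Pool list as from [soil_init()].
#' @param forcing List/one-row tibble with `temp` (deg C), `wfps` in
#'   `[0, 1]`, `ndep` (g N m^-2 yr^-1), `co2` (ppm).
#' @param params [soil_params()] list.
#' @return List with `state` (updated pools) and `fluxes` (g N m^-2 yr^-1):
#'   per-pathway N2O (`n2o_nit_auto`, `n2o_nit_het`, `n2o_nitden`,
#'   `n2o_denden`), `n2o` total, `n2`, `uptake_net`, `mineralization`,
#'   `nitrification`, `denitrification`.
#' @export
soil_step <- function(state, forcing, params = soil_params()) {
  validate_soil_params(params)
  if (any(forcing$wfps < 0 | forcing$wfps > 1)) {
    abort("WFPS must lie in [0, 1].", class = "n2o_domain_error")
  }
  if (any(forcing$co2 <= 0)) {
    abort("CO2 must be positive.", class = "n2o_domain_error")
  }
  if (any(forcing$ndep < 0)) {
    abort("N deposition must be non-negative.", class = "n2o_domain_error")
  }
  soil_step_core(state, forcing$temp, forcing$wfps, forcing$ndep,
                 forcing$co2, params)
}

# unvalidated inner step shared by soil_step() and the tight-loop drivers
#' @keywords internal
soil_step_core <- function(state, temp, wfps, ndep, co2, params) {
  nh4 <- state$nh4; no3 <- state$no3; son <- state$son
  lc <- state$labile_c

  f_t <- params$q10^((temp - params$t_ref) / 10)
  f_w <- pmax(0, 1 - ((wfps - params$wfps_opt) / params$wfps_width)^2)
  env <- f_t * f_w

  # 1. mineralization
  mineral <- son * (1 - exp(-params$k_min * f_t))
  son <- son - mineral
  nh4 <- nh4 + mineral
  # 2. deposition
  nh4 <- nh4 + ndep / 2
  no3 <- no3 + ndep / 2
  # 3. ammonium oxidation (autotrophic nitrification + nitrifier denitr.)
  nit <- nh4 * (1 - exp(-params$k_nit_auto * env))
  n2o_na <- params$y_nit_auto * nit
  n2o_nd <- params$y_nitden * nit
  nh4 <- nh4 - nit
  no3 <- no3 + nit - n2o_na - n2o_nd
  # 4. heterotrophic nitrification on organic N
  het <- son * (1 - exp(-params$k_nit_het * env))
  n2o_nh <- params$y_nit_het * het
  son <- son - het
  no3 <- no3 + het - n2o_nh
  # 5. denitrification
  den <- no3 * (1 - exp(-params$k_den * lc * env))
  n2o_dd <- params$y_denden * den
  n2 <- den - n2o_dd
  no3 <- no3 - den
  # 6. plant uptake with CO2 fertilization; litter share returns to SON
  u_co2 <- pmax(0, 1 + params$beta * log(co2 / params$co2_ref))
  ufrac <- 1 - exp(-params$k_up * u_co2)
  up_nh4 <- nh4 * ufrac
  up_no3 <- no3 * ufrac
  uptake <- up_nh4 + up_no3
  nh4 <- nh4 - up_nh4
  no3 <- no3 - up_no3
  son <- son + params$litter_frac * uptake
  uptake_net <- (1 - params$litter_frac) * uptake

  n2o <- n2o_na + n2o_nd + n2o_nh + n2o_dd
  list(
    state = list(nh4 = nh4, no3 = no3, son = son, labile_c = lc),
    fluxes = list(
      n2o_nit_auto = n2o_na, n2o_nit_het = n2o_nh,
      n2o_nitden = n2o_nd, n2o_denden = n2o_dd,
      n2o = n2o, n2 = n2, uptake_net = uptake_net,
      mineralization = mineral, nitrification = nit, denitrification = den
    )
  )
}

#' One annual step of the two-pathway model variant
#'
#' Identical numerics to [soil_step()] with only autotrophic nitrification
#' and denitrifier denitrification active: the heterotrophic-nitrification
#' and nitrifier-denitrification yields are forced to zero.
#' @inheritParams soil_step
#' @return As [soil_step()].
#' @export
soil_step_two_pathway <- function(state, forcing, params = soil_params()) {
  params$y_nit_het <- 0
  params$y_nitden <- 0
  soil_step(state, forcing, params)
}

#' Build an abstract equal-area 25-km grid
#'
#' Cells are laid out on an abstract lattice (no map projection); each cell
#' is exactly 25 km x 25 km = 6.25e8 m^2, so areas are exact by
#' construction. The land-cover mask admits only forest and grassland.
#'
#' @param n_forest,n_grass Number of forest and grassland cells.
#' @return Tibble with `cell_id`, `x`, `y` (cell-center km), `landcover`,
#'   `area_m2`.
#' @export
make_grid <- function(n_forest, n_grass) {
  n <- n_forest + n_grass
  if (n == 0L) {
    return(tibble(cell_id = integer(), x = numeric(), y = numeric(),
                  landcover = character(), area_m2 = numeric()))
  }
  nx <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  tibble(
    cell_id = seq_len(n),
    x = (idx %% nx) * 25 + 12.5,
    y = (idx %/% nx) * 25 + 12.5,
    landcover = c(rep("forest", n_forest), rep("grassland", n_grass)),
    area_m2 = 25000^2
  )
}

#' Simulate the soil model over a grid and period
#'
#' Runs the annual model for every cell (vectorized across cells), after an
#' optional spin-up that repeats the first year's forcing to bring pools
#' near steady state. Per-cell fluxes are multiplied by the exact cell area
#' and summed to national and land-cover totals in Gg N2O per year.
#'
#' @param grid Grid tibble from [make_grid()].
#' @param forcings Long tibble with `cell_id`, `year`, `temp`, `wfps`,
#'   `ndep`, `co2` covering every cell and every year.
#' @param params [soil_params()] list.
#' @param years Integer years to simulate (default: all years in
#'   `forcings`).
#' @param spinup_years Years of spin-up on the first year's forcing
#'   (default 200, enough for the slow organic-N pool to settle).
#' @param two_pathway Use the two-pathway variant.
#' @return List with `national` (tibble `year`, `landcover`, `n2o_gg`,
#'   plus a `"total"` land cover), `cells` (tibble `cell_id`, `year`,
#'   `flux_gn_m2`, per-pathway fluxes), and the final `state`.
#' @export
simulate_grid <- function(grid, forcings, params = soil_params(),
                          years = NULL, spinup_years = 200,
                          two_pathway = FALSE) {
  if (is.null(years)) years <- sort(unique(forcings$year))
  years <- as.integer(years)
  if (nrow(grid) == 0L) {
    return(list(
      national = tibble(year = rep(years, each = 1), landcover = "total",
                        n2o_gg = 0),
      cells = tibble(), state = NULL
    ))
  }
  f <- forcings[order(forcings$year, forcings$cell_id), ]
  missing_years <- setdiff(years, unique(f$year))
  if (length(missing_years) > 0) {
    abort(paste0("Forcings missing for year(s): ",
                 paste(missing_years, collapse = ", ")),
          class = "n2o_config_error")
  }
  step_fn <- if (two_pathway) soil_step_two_pathway else soil_step
  grid <- grid[order(grid$cell_id), ]
  yearly <- split(f, f$year)
  for (y in as.character(years)) {
    fy <- yearly[[y]]
    if (is.null(fy) || nrow(fy) != nrow(grid) ||
        !all(fy$cell_id == grid$cell_id)) {
      abort(paste0("Forcings for year ", y, " do not cover the grid."),
            class = "n2o_config_error")
    }
  }
  state <- soil_init(grid$landcover)
  if (spinup_years > 0) {
    f0 <- yearly[[as.character(years[1])]]
    for (i in seq_len(spinup_years)) state <- step_fn(state, f0, params)$state
  }
  ncell <- nrow(grid)
  flux <- matrix(0, nrow = ncell, ncol = length(years))
  path <- array(0, dim = c(ncell, length(years), 4),
                dimnames = list(NULL, NULL,
                                c("n2o_nit_auto", "n2o_nit_het",
                                  "n2o_nitden", "n2o_denden")))
  for (k in seq_along(years)) {
    res <- step_fn(state, yearly[[as.character(years[k])]], params)
    state <- res$state
    flux[, k] <- res$fluxes$n2o
    for (p in dimnames(path)[[3]]) path[, k, p] <- res$fluxes[[p]]
  }
  # g N m^-2 * m^2 = g N; 1 Gg = 1e9 g; report as Gg N2O
  to_gg_n2o <- function(gn) n2o_n_to_n2o(gn / 1e9)
  cell_tbl <- tibble(
    cell_id = rep(grid$cell_id, times = length(years)),
    year = rep(years, each = ncell),
    landcover = rep(grid$landcover, times = length(years)),
    flux_gn_m2 = as.vector(flux),
    n2o_nit_auto = as.vector(path[, , "n2o_nit_auto"]),
    n2o_nit_het = as.vector(path[, , "n2o_nit_het"]),
    n2o_nitden = as.vector(path[, , "n2o_nitden"]),
    n2o_denden = as.vector(path[, , "n2o_denden"])
  )
  area <- grid$area_m2
  by_lc <- cell_tbl |>
    dplyr::mutate(gn = .data$flux_gn_m2 * rep(area, times = length(years))) |>
    dplyr::group_by(.data$year, .data$landcover) |>
    dplyr::summarise(n2o_gg = to_gg_n2o(sum(.data$gn)), .groups = "drop")
  total <- by_lc |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(n2o_gg = sum(.data$n2o_gg), .groups = "drop") |>
    dplyr::mutate(landcover = "total")
  list(national = dplyr::bind_rows(by_lc, total[c("year", "landcover", "n2o_gg")]),
       cells = cell_tbl, state = state)
}

#' Factorial driver-attribution experiments
#'
#' Runs the all-drivers simulation S_ALL plus one counterfactual per driver
#' (CO2, N deposition, climate = temperature + WFPS) with that driver held
#' at its first-year value in every cell. The contribution of driver X is
#' the trend-integrated difference of the national series,
#' `slope(S_ALL - S_fix(X)) * (n_years)`, in Gg N2O per year of annual
#' emission attributable to X over the window; the multiplier follows the
#' accumulated-change convention of [linear_trend()]. Non-additivity of the
#' decomposition is reported explicitly as a residual row.
#'
#' @inheritParams simulate_grid
#' @param trend_multiplier Years multiplier for the accumulated change
#'   (default 41 for a 1980-2020 window).
#' @return List with `contributions` (tibble `driver`, `contribution_gg`,
#'   including a `residual` row), `series` (national totals per run).
#' @export
factorial_experiments <- function(grid, forcings, params = soil_params(),
                                  years = NULL, spinup_years = 200,
                                  trend_multiplier = 41) {
  if (is.null(years)) years <- sort(unique(forcings$year))
  y0 <- min(years)
  base_year <- forcings[forcings$year == y0,
                        c("cell_id", "temp", "wfps", "ndep", "co2")]
  fix <- function(vars) {
    f <- forcings
    j <- match(f$cell_id, base_year$cell_id)
    for (v in vars) f[[v]] <- base_year[[v]][j]
    f
  }
  runs <- list(
    all = forcings,
    fix_co2 = fix("co2"),
    fix_ndep = fix("ndep"),
    fix_clim = fix(c("temp", "wfps"))
  )
  nat <- lapply(runs, function(f) {
    s <- simulate_grid(grid, f, params, years = years,
                       spinup_years = spinup_years)$national
    s[s$landcover == "total", c("year", "n2o_gg")]
  })
  acc <- function(series) {
    unname(stats::coef(stats::lm(n2o_gg ~ year, data = series))["year"]) *
      trend_multiplier
  }
  delta_acc <- vapply(c("fix_co2", "fix_ndep", "fix_clim"), function(r) {
    d <- nat$all
    d$n2o_gg <- nat$all$n2o_gg - nat[[r]]$n2o_gg
    acc(d)
  }, numeric(1))
  contributions <- tibble(
    driver = c("co2", "ndep", "clim", "residual"),
    contribution_gg = c(unname(delta_acc),
                        acc(nat$all) - sum(delta_acc))
  )
  series <- dplyr::bind_rows(lapply(names(nat), function(r) {
    dplyr::mutate(nat[[r]], run = r)
  }))
  list(contributions = contributions, series = series)
}
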