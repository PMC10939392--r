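empty_state <- function(n = 1) {
  list(nh4 = rep(0, n), no3 = rep(0, n), son = rep(0, n),
       labile_c = rep(1, n))
}

test_that("no substrate and no deposition give zero flux", {
  f <- list(temp = 12, wfps = 0.6, ndep = 0, co2 = 380)
  out <- soil_step(empty_state(), f)
  expect_equal(out$fluxes$n2o, 0)
  expect_equal(soil_step_two_pathway(empty_state(), f)$fluxes$n2o, 0)
})

test_that("nitrogen mass balance closes at every step", {
  set.seed(101)
  n <- 200
  for (rep in 1:10) {
    state <- list(nh4 = stats::runif(n, 0, 5), no3 = stats::runif(n, 0, 5),
                  son = stats::runif(n, 0, 500),
                  labile_c = stats::runif(n, 0.2, 1.5))
    f <- list(temp = stats::runif(n, -5, 30), wfps = stats::runif(n, 0, 1),
              ndep = stats::runif(n, 0, 4), co2 = stats::runif(n, 280, 600))
    before <- state$nh4 + state$no3 + state$son
    out <- soil_step(state, f)
    after <- out$state$nh4 + out$state$no3 + out$state$son
    outputs <- out$fluxes$n2o + out$fluxes$n2 + out$fluxes$uptake_net
    expect_true(all(abs(f$ndep - outputs - (after - before)) < 1e-9))
  }
})

test_that("pools and fluxes stay non-negative under random forcing sequences", {
  set.seed(202)
  for (rep in 1:5) {
    state <- soil_init(sample(c("forest", "grassland"), 1))
    for (step in 1:30) {
      f <- list(temp = stats::runif(1, -10, 35), wfps = stats::runif(1),
                ndep = stats::runif(1, 0, 5), co2 = stats::runif(1, 200, 800))
      out <- soil_step(state, f)
      expect_true(all(unlist(out$state) >= 0))
      expect_true(all(unlist(out$fluxes) >= 0))
      state <- out$state
    }
  }
})

test_that("the four-pathway model with two yields zeroed is the two-pathway model", {
  set.seed(303)
  state <- list(nh4 = stats::runif(5, 0, 3), no3 = stats::runif(5, 0, 3),
                son = stats::runif(5, 50, 400), labile_c = rep(1, 5))
  f <- list(temp = stats::runif(5, 0, 25), wfps = stats::runif(5, 0.2, 0.9),
            ndep = stats::runif(5, 0, 3), co2 = rep(400, 5))
  p <- soil_params(y_nit_het = 0, y_nitden = 0)
  a <- soil_step(state, f, p)
  b <- soil_step_two_pathway(state, f, soil_params())
  expect_identical(a, b)
})

test_that("warming raises the flux within the Q10 regime", {
  state <- soil_init("forest")
  cool <- soil_step_two_pathway(state, list(temp = 8, wfps = 0.6, ndep = 1,
                                            co2 = 360))
  warm <- soil_step_two_pathway(state, list(temp = 12, wfps = 0.6, ndep = 1,
                                            co2 = 360))
  expect_gt(warm$fluxes$n2o, cool$fluxes$n2o)
})

test_that("N deposition and CO2 shift cumulative emissions in opposite directions", {
  f <- constant_forcing(41, temp = 10, wfps = 0.6, ndep = 1, co2 = 340)
  s0 <- soil_init("forest")
  base <- sum(simulate_cell(s0, f, spinup_years = 20))
  f2 <- f; f2$ndep <- 2 * f2$ndep
  expect_gt(sum(simulate_cell(s0, f2, spinup_years = 20)), base)
  # CO2 ramp with beta > 0 lowers cumulative N2O
  f3 <- f; f3$co2 <- seq(340, 412, length.out = 41)
  ramp <- simulate_cell(s0, f3, spinup_years = 20)
  expect_lt(sum(ramp), base)
  # and with beta = 0 the ramp has no effect
  p0 <- soil_params(beta = 0)
  expect_equal(sum(simulate_cell(s0, f3, p0, spinup_years = 20)),
               sum(simulate_cell(s0, f, p0, spinup_years = 20)))
})

test_that("grid totals are flux times exact cell area", {
  grid <- make_grid(1, 0)
  f <- dplyr::mutate(constant_forcing(3, years = 2000:2002), cell_id = 1L)
  sim <- simulate_grid(grid, f, spinup_years = 5)
  cell_flux <- sim$cells$flux_gn_m2
  nat <- sim$national[sim$national$landcover == "total", ]
  expect_equal(nat$n2o_gg, cell_flux * 6.25e8 / 1e9 * 44 / 28,
               tolerance = 1e-12)
  # empty mask
  empty <- simulate_grid(make_grid(0, 0), f[0, ], years = 2000:2002)
  expect_true(all(empty$national$n2o_gg == 0))
})

test_that("disjoint masks add and missing forcing years are reported", {
  grid <- make_grid(2, 2)
  set.seed(7)
  f <- dplyr::bind_rows(lapply(2000:2004, function(y) {
    tibble::tibble(cell_id = grid$cell_id, year = y,
                   temp = stats::runif(4, 5, 15), wfps = 0.6,
                   ndep = stats::runif(4, 0.5, 1.5), co2 = 380)
  }))
  whole <- simulate_grid(grid, f, spinup_years = 10)
  parts <- lapply(list(1:2, 3:4), function(i) {
    simulate_grid(grid[i, ], f[f$cell_id %in% i, ], spinup_years = 10)
  })
  tot <- function(s) s$national$n2o_gg[s$national$landcover == "total"]
  expect_equal(tot(parts[[1]]) + tot(parts[[2]]), tot(whole),
               tolerance = 1e-9)
  expect_error(simulate_grid(grid, f[f$year != 2002, ], years = 2000:2004),
               class = "n2o_config_error")
})

test_that("factorial attribution isolates the driver that actually varied", {
  grid <- make_grid(3, 2)
  years <- 2000:2014
  set.seed(31)
  base <- tibble::tibble(cell_id = rep(grid$cell_id, length(years)),
                         year = rep(years, each = nrow(grid)),
                         temp = 10, wfps = 0.6, ndep = 1, co2 = 360)
  # all drivers constant: every contribution is zero
  fx0 <- factorial_experiments(grid, base, years = years, spinup_years = 400,
                               trend_multiplier = length(years))
  drv <- fx0$contributions
  expect_equal(drv$contribution_gg[drv$driver %in% c("co2", "ndep", "clim")],
               rep(0, 3))
  # only N deposition varies
  f_nd <- base
  f_nd$ndep <- 1 + 0.05 * (f_nd$year - 2000)
  fx <- factorial_experiments(grid, f_nd, years = years, spinup_years = 400,
                              trend_multiplier = length(years))
  drv <- fx$contributions
  expect_equal(drv$contribution_gg[drv$driver %in% c("co2", "clim")],
               rep(0, 2))
  expect_gt(drv$contribution_gg[drv$driver == "ndep"], 0)
  # the isolated driver explains the whole trend up to the transient residual
  expect_lt(abs(drv$contribution_gg[drv$driver == "residual"]),
            0.1 * drv$contribution_gg[drv$driver == "ndep"] + 1e-6)
})

test_that("soil parameter validation rejects out-of-range values", {
  expect_error(soil_params(y_denden = 1.2), class = "n2o_domain_error")
  expect_error(soil_params(beta = -1), class = "n2o_domain_error")
  expect_error(soil_params(nonsense = 1), class = "n2o_domain_error")
  expect_error(soil_step(soil_init("forest"),
                         list(temp = 10, wfps = 1.5, ndep = 0, co2 = 400)),
               class = "n2o_domain_error")
})
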