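one_cat_inventory <- function(value = 100, ef_cv = 0.2, ad_cv = 0,
                              category = "adipic_acid",
                              sector = "industry") {
  tibble::tibble(year = 2020L, province = "Henan", sector = sector,
                 category = category, n2o_n_gg = value,
                 ad_dist = "normal", ad_cv = ad_cv,
                 ef_dist = "lognormal", ef_cv = ef_cv)
}

test_that("degenerate dispersion collapses the interval to the point value", {
  res <- propagate(one_cat_inventory(ef_cv = 0), n_draws = 100, seed = 1)
  nat <- res$national
  expect_equal(nat$ci_low, nat$mean)
  expect_equal(nat$ci_high, nat$mean)
  expect_equal(nat$mean, n2o_n_to_n2o(100))
})

test_that("propagation is reproducible under a fixed seed and ordered", {
  inv <- one_cat_inventory(ef_cv = 0.3, ad_cv = 0.1)
  a <- propagate(inv, n_draws = 500, seed = 42)
  b <- propagate(inv, n_draws = 500, seed = 42)
  expect_identical(a, b)
  c <- propagate(inv, n_draws = 500, seed = 43)
  expect_false(identical(a$national$mean, c$national$mean))
  expect_true(all(a$national$ci_low <= a$national$mean))
  expect_true(all(a$national$mean <= a$national$ci_high))
})

test_that("lognormal EF intervals match the closed-form quantiles", {
  inv <- one_cat_inventory(value = 100, ef_cv = 0.2)
  res <- propagate(inv, n_draws = 1e4, seed = 7)
  nat <- res$national
  sdlog <- sqrt(log(1 + 0.2^2))
  q <- stats::qlnorm(c(0.025, 0.975), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  expected <- n2o_n_to_n2o(100 * q)
  expect_lt(abs(nat$ci_low - expected[1]) / expected[1], 0.02)
  expect_lt(abs(nat$ci_high - expected[2]) / expected[2], 0.02)
  # the deterministic value lies inside the interval
  expect_lt(nat$ci_low, n2o_n_to_n2o(100))
  expect_gt(nat$ci_high, n2o_n_to_n2o(100))
  # lognormal skew: upper arm longer than lower arm
  expect_gt(nat$ci_high - nat$mean, nat$mean - nat$ci_low)
})

test_that("independent category EFs add in variance; shared EFs correlate", {
  inv2 <- dplyr::bind_rows(
    one_cat_inventory(50, ef_cv = 0.2, category = "adipic_acid"),
    one_cat_inventory(80, ef_cv = 0.2, category = "nitric_acid"))
  # recover the draw-level variance from a manual re-run of the draws
  set.seed(99)
  n <- 2e4
  v1 <- 50 * draw_uncertainty(n, "lognormal", 0.2)
  v2 <- 80 * draw_uncertainty(n, "lognormal", 0.2)
  expect_equal(stats::var(v1 + v2), stats::var(v1) + stats::var(v2),
               tolerance = 0.05 * stats::var(v1 + v2))
  # within a category, provinces share one EF draw: totals scale linearly
  inv_shared <- dplyr::bind_rows(
    one_cat_inventory(50), dplyr::mutate(one_cat_inventory(80),
                                         province = "Liaoning"))
  res <- propagate(inv_shared, n_draws = 4000, seed = 3)
  one <- propagate(one_cat_inventory(130), n_draws = 4000, seed = 3)
  expect_equal(res$national$ci_high, one$national$ci_high, tolerance = 1e-9)
})

test_that("invalid distribution specs fail before sampling", {
  inv <- dplyr::mutate(one_cat_inventory(), ef_dist = "cauchy")
  expect_error(propagate(inv, n_draws = 10, seed = 1),
               class = "n2o_domain_error")
  expect_error(propagate(one_cat_inventory(), n_draws = 1, seed = 1),
               class = "n2o_domain_error")
  expect_error(draw_uncertainty(5, "uniform", low = 2, high = 1),
               class = "n2o_domain_error")
})

test_that("triangular and uniform multipliers respect their supports", {
  set.seed(5)
  u <- draw_uncertainty(5000, "uniform", low = 0.5, high = 1.5)
  expect_true(all(u >= 0.5 & u <= 1.5))
  tr <- draw_uncertainty(5000, "triangular", low = 0.6, high = 1.8)
  expect_true(all(tr >= 0.6 & tr <= 1.8))
  # triangular mean = (low + mode + high)/3
  expect_equal(mean(tr), (0.6 + 1 + 1.8) / 3, tolerance = 0.02)
})

test_that("the cell fast path reproduces repeated full steps", {
  set.seed(91)
  f <- tibble::tibble(year = 1:30, temp = stats::runif(30, 0, 25),
                      wfps = stats::runif(30, 0.2, 0.95),
                      ndep = stats::runif(30, 0, 3),
                      co2 = stats::runif(30, 300, 500))
  s0 <- soil_init("forest")
  p <- soil_params()
  fast <- simulate_cell(s0, f, p, spinup_years = 7)
  state <- s0
  for (i in 1:7) state <- soil_step(state, lapply(f, `[`, 1), p)$state
  slow <- numeric(30)
  for (i in 1:30) {
    r <- soil_step(state, lapply(f, `[`, i), p)
    state <- r$state
    slow[i] <- r$fluxes$n2o
  }
  expect_equal(fast, slow, tolerance = 1e-12)
})

mcmc_setup <- function(seed, sigma_frac = 0.05, n_years = 41) {
  p_true <- soil_params()
  f <- constant_forcing(n_years, temp = 10, wfps = 0.6, co2 = 340)
  f$ndep <- 1 + 0.02 * seq_len(n_years)
  s0 <- soil_init("forest")
  truth <- simulate_cell(s0, f, p_true, spinup_years = 10)
  set.seed(seed)
  sigma <- sigma_frac * mean(truth)
  obs <- truth + stats::rnorm(n_years, 0, sigma)
  list(obs = obs, forcing = f, s0 = s0, sigma = sigma, params = p_true)
}

test_that("a zero-scale proposal never moves and accepts every no-op", {
  su <- mcmc_setup(1)
  fit <- mcmc_fit(su$obs, su$forcing, su$s0, su$params,
                  fit = c(y_denden = 0.06),
                  priors = list(y_denden = function(x)
                    stats::dunif(x, 0, 0.5)),
                  proposal_sd = c(y_denden = 0),
                  sigma_obs = su$sigma, n_iter = 50, seed = 2)
  expect_equal(fit$acceptance_rate, 1)
  expect_true(all(fit$samples[, "y_denden"] == 0.06))
})

test_that("a zero-probability starting point is rejected up front", {
  su <- mcmc_setup(1)
  expect_error(
    mcmc_fit(su$obs, su$forcing, su$s0, su$params,
             fit = c(y_denden = 0.9),
             priors = list(y_denden = function(x) stats::dunif(x, 0, 0.5)),
             proposal_sd = c(y_denden = 0.01),
             sigma_obs = su$sigma, n_iter = 10, seed = 2),
    class = "n2o_domain_error")
})

test_that("with a flat likelihood the posterior reproduces the prior", {
  su <- mcmc_setup(3)
  prior_lo <- 0.01; prior_hi <- 0.11
  fit <- mcmc_fit(su$obs, su$forcing, su$s0, su$params,
                  fit = c(y_denden = 0.06),
                  priors = list(y_denden = function(x)
                    stats::dunif(x, prior_lo, prior_hi)),
                  proposal_sd = c(y_denden = 0.03),
                  sigma_obs = 1e9, # effectively no information
                  n_iter = 6000, seed = 4)
  qs <- stats::quantile(fit$samples[, "y_denden"], c(0.25, 0.5, 0.75))
  expected <- prior_lo + c(0.25, 0.5, 0.75) * (prior_hi - prior_lo)
  expect_true(all(abs(qs - expected) < 0.012))
})

test_that("the chain recovers known parameters from synthetic observations", {
  su <- mcmc_setup(11)
  fit <- mcmc_fit(su$obs, su$forcing, su$s0, su$params,
                  fit = c(y_denden = 0.04, k_den = 0.5),
                  priors = list(
                    y_denden = function(x) stats::dunif(x, 0.005, 0.3),
                    k_den = function(x) stats::dlnorm(x, log(0.7), 0.7)),
                  proposal_sd = c(y_denden = 0.006, k_den = 0.08),
                  sigma_obs = su$sigma, n_iter = 2000, seed = 12)
  ci_y <- stats::quantile(fit$samples[, "y_denden"], c(0.025, 0.975))
  ci_k <- stats::quantile(fit$samples[, "k_den"], c(0.025, 0.975))
  expect_true(ci_y[1] <= 0.06 && 0.06 <= ci_y[2])
  expect_true(ci_k[1] <= 0.7 && 0.7 <= ci_k[2])
  expect_gt(fit$acceptance_rate, 0.05)
  expect_lt(fit$acceptance_rate, 0.8)
})
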