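#' Draw multiplicative uncertainty factors
#'
#' Distributions are parameterized so the draw has nominal value 1 (mean 1
#' for normal and lognormal; mode 1 for triangular), multiplying the
#' nominal quantity:
#' - `normal`: mean 1, sd = CV, truncated at 0 by resampling;
#' - `lognormal`: `sdlog = sqrt(log(1 + cv^2))`, `meanlog = -sdlog^2/2`
#'   (mean exactly 1);
#' - `uniform`: on `[low, high]` relative to the nominal;
#' - `triangular`: mode 1, support `[low, high]`, inverse-CDF sampling.
#'
#' @param n Number of draws.
#' @param distribution One of `normal`, `lognormal`, `uniform`,
#'   `triangular`.
#' @param cv Coefficient of variation (normal/lognormal).
#' @param low,high Relative bounds (uniform/triangular).
#' @return Numeric vector of n non-negative multipliers.
#' @export
draw_uncertainty <- function(n, distribution = "lognormal", cv = 0,
                             low = NA, high = NA) {
  if (!distribution %in% c("normal", "lognormal", "uniform", "triangular")) {
    abort(paste0("Unknown distribution '", distribution, "'."),
          class = "n2o_domain_error")
  }
  if (distribution %in% c("normal", "lognormal")) {
    if (is.na(cv) || cv < 0) {
      abort("CV must be a non-negative number.", class = "n2o_domain_error")
    }
    if (cv == 0) return(rep(1, n))
    if (distribution == "normal") {
      x <- stats::rnorm(n, 1, cv)
      while (any(x <= 0)) {
        x[x <= 0] <- stats::rnorm(sum(x <= 0), 1, cv)
      }
      return(x)
    }
    sdlog <- sqrt(log(1 + cv^2))
    return(stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  if (is.na(low) || is.na(high) || low > high || low < 0) {
    abort("uniform/triangular draws need 0 <= low <= high.",
          class = "n2o_domain_error")
  }
  if (distribution == "uniform") return(stats::runif(n, low, high))
  rtriangular(n, low, 1, high)
}

#' @keywords internal
rtriangular <- function(n, low, mode, high) {
  if (low == high) return(rep(low, n))
  mode <- min(max(mode, low), high)
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

#' Monte Carlo propagation of inventory uncertainty
#'
#' Redraws the full inventory `n_draws` times. Activity data are
#' observations per province and are drawn independently per row
#' (truncated-normal by default); EFs are national parameters shared across
#' provinces, so one EF multiplier per category is drawn per iteration —
#' perfectly correlated within a category, independent across categories.
#' Every draw recomputes the inventory (the engine is linear in AD and EF,
#' so each row's draw is `value * ad_mult * ef_mult`), and empirical
#' 2.5/97.5 percentiles of the aggregates form the 95% intervals.
#'
#' @param inventory Emission-estimate tibble with columns `year`,
#'   `province`, `sector`, `category`, `n2o_n_gg`, plus optional
#'   uncertainty tags `ad_dist`, `ad_cv`, `ef_dist`, `ef_cv`, `ef_low`,
#'   `ef_high` (defaults: AD truncated-normal CV 0, EF lognormal CV 0).
#' @param n_draws Number of Monte Carlo draws (>= 2).
#' @param seed Integer seed; identical seed gives identical output.
#' @return List with tibbles `national` (per year), `by_sector` (per
#'   year/sector), `by_category` (per year/category), each with `mean`,
#'   `ci_low`, `ci_high` in Gg N2O, and `n_draws`.
#' @export
propagate <- function(inventory, n_draws = 1000, seed = 1L) {
  if (n_draws < 2) {
    abort("n_draws must be at least 2.", class = "n2o_domain_error")
  }
  inv <- inventory
  defaults <- list(ad_dist = "normal", ad_cv = 0, ef_dist = "lognormal",
                   ef_cv = 0, ef_low = NA_real_, ef_high = NA_real_)
  for (col in names(defaults)) {
    if (!col %in% names(inv)) inv[[col]] <- defaults[[col]]
  }
  bad <- !inv$ef_dist %in% c("normal", "lognormal", "uniform", "triangular") |
    !inv$ad_dist %in% c("normal", "lognormal", "uniform", "triangular")
  if (any(bad)) {
    abort("Invalid distribution tag in inventory.", class = "n2o_domain_error")
  }
  set.seed(as.integer(seed))
  n <- nrow(inv)
  cats <- unique(inv$category)
  cat_idx <- match(inv$category, cats)
  # one uncertainty spec per category for the EF draw
  ef_spec <- inv[!duplicated(inv$category),
                 c("category", "ef_dist", "ef_cv", "ef_low", "ef_high")]
  ef_spec <- ef_spec[match(cats, ef_spec$category), ]
  key_nat <- as.integer(factor(inv$year))
  key_sec <- as.integer(factor(paste(inv$year, inv$sector, sep = "\r")))
  key_cat <- as.integer(factor(paste(inv$year, inv$category, sep = "\r")))
  nat_draws <- matrix(0, max(key_nat), n_draws)
  sec_draws <- matrix(0, max(key_sec), n_draws)
  cat_draws <- matrix(0, max(key_cat), n_draws)
  for (d in seq_len(n_draws)) {
    ef_mult <- vapply(seq_along(cats), function(i) {
      draw_uncertainty(1, ef_spec$ef_dist[i], ef_spec$ef_cv[i],
                       ef_spec$ef_low[i], ef_spec$ef_high[i])
    }, numeric(1))
    ad_mult <- rep(1, n)
    vary <- inv$ad_cv > 0
    if (any(vary)) {
      # truncated normal per row (distribution tags honoured rowwise)
      for (dist in unique(inv$ad_dist[vary])) {
        rows <- which(vary & inv$ad_dist == dist)
        cvs <- unique(inv$ad_cv[rows])
        for (cv in cvs) {
          r <- rows[inv$ad_cv[rows] == cv]
          ad_mult[r] <- draw_uncertainty(length(r), dist, cv)
        }
      }
    }
    val <- inv$n2o_n_gg * ad_mult * ef_mult[cat_idx]
    nat_draws[, d] <- rowsum(val, key_nat)
    sec_draws[, d] <- rowsum(val, key_sec)
    cat_draws[, d] <- rowsum(val, key_cat)
  }
  summarize_draws <- function(draws, keys, labels) {
    qs <- t(apply(draws, 1, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE))
    out <- labels[!duplicated(keys), , drop = FALSE]
    out <- out[order(keys[!duplicated(keys)]), , drop = FALSE]
    out$mean <- n2o_n_to_n2o(rowMeans(draws))
    out$ci_low <- n2o_n_to_n2o(qs[, 1])
    out$ci_high <- n2o_n_to_n2o(qs[, 2])
    as_tibble(out)
  }
  list(
    national = summarize_draws(nat_draws, key_nat, inv[, "year"]),
    by_sector = summarize_draws(sec_draws, key_sec, inv[, c("year", "sector")]),
    by_category = summarize_draws(cat_draws, key_cat,
                                  inv[, c("year", "category")]),
    n_draws = n_draws
  )
}

#' Simulate one grid cell's annual N2O flux series
#'
#' Tight-loop driver for calibration: runs [soil_step()] over the rows of a
#' single-cell forcing table and returns the annual total N2O flux.
#'
#' @param state0 Initial pools ([soil_init()]).
#' @param forcing Tibble with one row per year (`temp`, `wfps`, `ndep`,
#'   `co2`).
#' @param params [soil_params()] list.
#' @param spinup_years Spin-up repetitions of the first row's forcing.
#' @return Numeric vector of annual N2O fluxes (g N m^-2 yr^-1).
#' @export
simulate_cell <- function(state0, forcing, params = soil_params(),
                          spinup_years = 0) {
  validate_soil_params(params)
  if (any(forcing$wfps < 0 | forcing$wfps > 1) || any(forcing$co2 <= 0) ||
      any(forcing$ndep < 0)) {
    abort("Forcing out of range (WFPS in [0,1], CO2 > 0, ndep >= 0).",
          class = "n2o_domain_error")
  }
  # scalar fast path: the same update rule as soil_step_core(), written
  # allocation-free for the MCMC inner loop; equivalence is covered by a
  # regression test against repeated soil_step() calls
  nh4 <- state0$nh4[1]; no3 <- state0$no3[1]; son <- state0$son[1]
  lc <- state0$labile_c[1]
  temp <- forcing$temp; wfps <- forcing$wfps
  ndep <- forcing$ndep; co2 <- forcing$co2
  q10 <- params$q10; t_ref <- params$t_ref
  w_opt <- params$wfps_opt; w_wid <- params$wfps_width
  k_min <- params$k_min; k_na <- params$k_nit_auto
  k_nh <- params$k_nit_het; k_den <- params$k_den; k_up <- params$k_up
  y_na <- params$y_nit_auto; y_nh <- params$y_nit_het
  y_nd <- params$y_nitden; y_dd <- params$y_denden
  beta <- params$beta; co2_ref <- params$co2_ref
  litf <- params$litter_frac
  n <- nrow(forcing)
  out <- numeric(n)
  total <- spinup_years + n
  for (step in seq_len(total)) {
    i <- if (step <= spinup_years) 1L else step - spinup_years
    f_t <- q10^((temp[i] - t_ref) / 10)
    f_w <- 1 - ((wfps[i] - w_opt) / w_wid)^2
    if (f_w < 0) f_w <- 0
    env <- f_t * f_w
    mineral <- son * (1 - exp(-k_min * f_t))
    son <- son - mineral
    nh4 <- nh4 + mineral + ndep[i] / 2
    no3 <- no3 + ndep[i] / 2
    nit <- nh4 * (1 - exp(-k_na * env))
    nh4 <- nh4 - nit
    no3 <- no3 + nit * (1 - y_na - y_nd)
    het <- son * (1 - exp(-k_nh * env))
    son <- son - het
    no3 <- no3 + het * (1 - y_nh)
    den <- no3 * (1 - exp(-k_den * lc * env))
    no3 <- no3 - den
    u_co2 <- 1 + beta * log(co2[i] / co2_ref)
    if (u_co2 < 0) u_co2 <- 0
    ufrac <- 1 - exp(-k_up * u_co2)
    uptake <- (nh4 + no3) * ufrac
    nh4 <- nh4 * (1 - ufrac)
    no3 <- no3 * (1 - ufrac)
    son <- son + litf * uptake
    if (step > spinup_years) {
      out[i] <- (y_na + y_nd) * nit + y_nh * het + y_dd * den
    }
  }
  out
}

#' MCMC calibration of soil-model parameters
#'
#' Random-walk Metropolis over a subset of soil parameters against observed
#' annual fluxes with a Gaussian noise model. Proposals are diagonal
#' Gaussian; a proposal standard deviation of zero makes the corresponding
#' coordinate a no-op. Parameters whose prior density is zero (outside
#' support) are rejected without model evaluation. Burn-in defaults to half
#' the chain; thinning keeps every `thin`-th post-burn-in sample.
#'
#' @param observations Numeric vector of observed annual N2O fluxes
#'   (g N m^-2 yr^-1).
#' @param forcing Single-cell forcing tibble aligned with `observations`.
#' @param state0 Initial pools.
#' @param params Full parameter list; entries not in `fit` stay fixed.
#' @param fit Named numeric vector of initial values for the parameters to
#'   estimate.
#' @param priors Named list of prior density functions (each takes the
#'   value, returns a density).
#' @param proposal_sd Named numeric vector of random-walk step sizes.
#' @param sigma_obs Observation noise standard deviation.
#' @param n_iter Chain length.
#' @param burn_in Iterations to discard (default `n_iter %/% 2`).
#' @param thin Thinning interval.
#' @param seed Integer seed.
#' @param spinup_years Spin-up before the observation window.
#' @return List with `samples` (matrix, one column per fitted parameter),
#'   `log_posterior`, `acceptance_rate`, `seed`.
#' @export
mcmc_fit <- function(observations, forcing, state0, params = soil_params(),
                     fit, priors, proposal_sd, sigma_obs,
                     n_iter = 4000, burn_in = NULL, thin = 1, seed = 1L,
                     spinup_years = 10) {
  if (is.null(burn_in)) burn_in <- n_iter %/% 2
  set.seed(as.integer(seed))
  pnames <- names(fit)
  stopifnot(all(pnames %in% names(params)),
            all(pnames %in% names(priors)),
            all(pnames %in% names(proposal_sd)))
  log_prior <- function(theta) {
    sum(vapply(pnames, function(p) log(priors[[p]](theta[[p]])), numeric(1)))
  }
  log_lik <- function(theta) {
    pp <- params
    pp[pnames] <- as.list(theta)
    ok <- tryCatch({ validate_soil_params(pp); TRUE },
                   error = function(e) FALSE)
    if (!ok) return(-Inf)
    pred <- simulate_cell(state0, forcing, pp, spinup_years = spinup_years)
    sum(stats::dnorm(observations, pred, sigma_obs, log = TRUE))
  }
  theta <- fit
  lp <- log_prior(theta)
  if (!is.finite(lp)) {
    abort("Initial value has zero prior probability.",
          class = "n2o_domain_error")
  }
  ll <- log_lik(theta)
  post <- lp + ll
  keep <- seq(burn_in + 1L, n_iter, by = thin)
  samples <- matrix(NA_real_, length(keep), length(fit),
                    dimnames = list(NULL, pnames))
  log_post_kept <- numeric(length(keep))
  accepted <- 0L
  k <- 0L
  for (i in seq_len(n_iter)) {
    prop <- theta + stats::rnorm(length(theta), 0, proposal_sd[pnames])
    lp_prop <- log_prior(prop)
    if (is.finite(lp_prop)) {
      post_prop <- lp_prop + log_lik(prop)
      if (is.finite(post_prop) &&
          log(stats::runif(1)) < post_prop - post) {
        theta <- prop
        post <- post_prop
        accepted <- accepted + 1L
      }
    }
    if (i > burn_in && ((i - burn_in - 1L) %% thin == 0L)) {
      k <- k + 1L
      samples[k, ] <- theta
      log_post_kept[k] <- post
    }
  }
  list(samples = samples, log_posterior = log_post_kept,
       acceptance_rate = accepted / n_iter, seed = as.integer(seed))
}
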