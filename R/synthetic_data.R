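#' Configuration for the synthetic series generator
#'
#' Bundles everything needed to generate a synthetic monthly three-tier
#' visit series with the statistical structure the fitting procedure
#' assumes: model parameters, an initial state, a horizon in years, a
#' relative observation-noise level, an optional 12-month seasonal
#' amplitude, and a seed.
#'
#' The defaults emulate the national study conditions: the
#' [reference_params()] values, an early-2010s-scale initial state (monthly
#' visits in 10,000s roughly 60\% of the 2019 tier averages), 8 calendar
#' years sampled January--November, and 2\% relative noise. Real series also
#' carry seasonal structure the model does not describe; `seasonal_amp`
#' exists so estimator robustness to such structure can be probed, and
#' defaults to 0.
#'
#' @param params A [visit_params()] object.
#' @param initial Non-negative starting state `c(x, y, z)`.
#' @param years Number of calendar years (11 observations each).
#' @param noise_sd Relative standard deviation of multiplicative Gaussian
#'   observation noise; non-negative.
#' @param seasonal_amp Relative amplitude of a 12-month sinusoid applied to
#'   observations; non-negative.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(params = reference_params(),
                             initial = c(1150, 6700, 10300),
                             years = 8, noise_sd = 0.02, seasonal_amp = 0,
                             seed = 20220426) {
  validate_params(params)
  validate_state(initial)
  if (years < 1 || years != round(years))
    stop("'years' must be a positive integer", call. = FALSE)
  if (noise_sd < 0 || seasonal_amp < 0)
    stop("'noise_sd' and 'seasonal_amp' must be non-negative", call. = FALSE)
  structure(list(params = params, initial = initial, years = as.integer(years),
                 noise_sd = noise_sd, seasonal_amp = seasonal_amp,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic monthly three-tier visit series
#'
#' Integrates the model from the configured initial state over
#' `years * 12` months on a monthly grid, keeps months 1--11 of each year
#' (December is dropped, matching the reporting gap of the national
#' series), and applies to each kept observation a seasonal factor
#' `1 + seasonal_amp * sin(2 * pi * month / 12)` and multiplicative noise
#' `1 + N(0, noise_sd^2)`, truncating at zero. With `noise_sd = 0` and
#' `seasonal_amp = 0` the series equals the model prediction to solver
#' tolerance. Identical configurations (including seed) give identical
#' series.
#'
#' @param config A [generator_config()] object.
#' @return A series data frame (columns `year`, `month`, `tier`,
#'   `visits_10k`; see [validate_series()]) with the config attached as
#'   attribute `"config"`.
#' @examples
#' obs <- generate_series(generator_config(years = 3, noise_sd = 0))
#' head(obs)
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  months <- seq(0, config$years * 12 - 1)
  tr <- integrate_visits(config$params, config$initial, months)
  month_in_year <- months %% 12 + 1
  keep <- month_in_year <= 11
  t_obs <- months[keep]
  Y <- as.matrix(tr[keep, c("x", "y", "z")])
  season <- 1 + config$seasonal_amp * sin(2 * pi * month_in_year[keep] / 12)
  noise <- if (config$noise_sd > 0)
    with_seed(config$seed,
              matrix(1 + stats::rnorm(length(Y), sd = config$noise_sd),
                     nrow = nrow(Y)))
  else 1
  Y <- pmax(Y * season * noise, 0)
  out <- data.frame(
    year = rep(as.integer(t_obs %/% 12 + 1), times = 3),
    month = rep(as.integer(t_obs %% 12 + 1), times = 3),
    tier = rep(tier_levels(), each = length(t_obs)),
    visits_10k = as.numeric(Y))
  attr(out, "config") <- config
  validate_series(out)
  out
}

#' Random valid parameter set
#'
#' Draws a parameter set from fixed ranges chosen to span the existence and
#' stability regimes: growth rates uniform on (0.02, 0.3)/month, capacities
#' log-uniform between about 30 and 30,000 (10,000 visits/month), churn
#' rates uniform on (0.001, 0.08)/month and leapfrog rates uniform on
#' (0, 0.08)/month. Draws land on the regime boundaries with probability
#' zero. Used by property tests and verification scripts.
#'
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A [visit_params()] object.
#' @export
random_params <- function(seed = NULL) {
  draw <- function() {
    visit_params(
      r_f = stats::runif(1, 0.02, 0.3),
      r_s = stats::runif(1, 0.02, 0.3),
      r_t = stats::runif(1, 0.02, 0.3),
      m_f = 10^stats::runif(1, 1.5, 4.5),
      m_s = 10^stats::runif(1, 1.5, 4.5),
      m_t = 10^stats::runif(1, 1.5, 4.5),
      c_f = stats::runif(1, 0.001, 0.08),
      c_s = stats::runif(1, 0.001, 0.08),
      c_t = stats::runif(1, 0.001, 0.08),
      alpha = stats::runif(1, 0, 0.08),
      beta = stats::runif(1, 0, 0.08),
      eta = stats::runif(1, 0, 0.08))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' National hospital resources and services, 2019
#'
#' Tier-level counts of hospitals, certified doctors, beds, and annual
#' visits (in 10,000s) for China's first-, second- and third-level
#' hospitals in 2019, together with the national totals. The table shows
#' the concentration of doctors, beds and visits in the upper tiers that
#' motivates the leapfrog terms of the model.
#'
#' @return A data frame with rows `FLH`, `SLH`, `TLH`, `Total` and columns
#'   `tier`, `hospitals`, `certified_doctors`, `beds`, `visits_10k`.
#' @examples
#' res <- hospital_resources_2019()
#' sum(res$visits_10k[res$tier != "Total"])  # equals the Total row
#' @export
hospital_resources_2019 <- function() {
  path <- system.file("extdata", "hospital_resources_2019.csv",
                      package = "tierdyn", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
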