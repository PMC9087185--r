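tier_levels <- function() c("FLH", "SLH", "TLH")

#' Validate an observed monthly visit series
#'
#' An observed series is a long-format data frame with columns `year`,
#' `month`, `tier` and `visits_10k`: one row per (year, month, tier), months
#' 1--11 of each year (the national series carry no December report), tiers
#' `"FLH"`, `"SLH"`, `"TLH"`, and non-negative counts in units of 10,000
#' visits/month. Every (year, month) present must carry all three tiers.
#'
#' @param series A data frame as above.
#' @return The series, invisibly, if valid; otherwise an error.
#' @export
validate_series <- function(series) {
  need <- c("year", "month", "tier", "visits_10k")
  if (!is.data.frame(series) || !all(need %in% names(series)))
    stop("series must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(series$tier %in% tier_levels()))
    stop("tier must be one of ", paste(tier_levels(), collapse = ", "),
         call. = FALSE)
  if (!all(series$month %in% 1:11))
    stop("month must be in 1..11 (December is not reported)", call. = FALSE)
  if (any(series$visits_10k < 0) || any(!is.finite(series$visits_10k)))
    stop("visits_10k must be finite and non-negative", call. = FALSE)
  tab <- table(series$year, series$month)
  if (any(tab != 3L))
    stop("every (year, month) must appear exactly once per tier",
         call. = FALSE)
  invisible(series)
}

# Wide view: times in months since the first observation, and a T x 3 matrix
# of counts ordered FLH, SLH, TLH.
series_matrix <- function(series) {
  validate_series(series)
  y0 <- min(series$year)
  t <- 12 * (series$year - y0) + (series$month - 1)
  ord <- order(t)
  times <- sort(unique(t))
  Y <- matrix(NA_real_, length(times), 3,
              dimnames = list(NULL, tier_levels()))
  for (k in tier_levels()) {
    sel <- series$tier == k
    Y[match(t[sel], times), k] <- series$visits_10k[sel]
  }
  list(times = times, Y = Y)
}

#' Model prediction at observation times
#'
#' Integrates the system from `initial` and samples it at the requested
#' times. The integration is continuous through unobserved months (e.g. the
#' December gaps of the national series); only the output grid is sparse.
#'
#' @param params A [visit_params()] object.
#' @param initial State at `times[1]`.
#' @param times Increasing observation times (months).
#' @param ... Passed to [integrate_visits()].
#' @return A matrix with one row per time and columns `FLH`, `SLH`, `TLH`.
#' @export
predict_visits <- function(params, initial, times, ...) {
  if (length(times) == 1L) {
    out <- matrix(initial, 1, 3, dimnames = list(NULL, tier_levels()))
    return(out)
  }
  tr <- integrate_visits(params, initial, times, ...)
  out <- as.matrix(tr[c("x", "y", "z")])
  colnames(out) <- tier_levels()
  out
}

#' Pooled coefficient of determination
#'
#' `R^2 = 1 - SSE / SST`, pooled over all tiers and times, with the total
#' sum of squares taken about the pooled grand mean of all observations.
#' A single pooled value is reported because the fit minimizes a single
#' pooled sum of squares across the three tiers.
#'
#' @param observed A series data frame (see [validate_series()]) or a
#'   numeric matrix/vector of observations.
#' @param predicted Predictions with the same shape as the observations.
#' @return The pooled R-squared.
#' @examples
#' r_squared(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))  # 0.98
#' @export
r_squared <- function(observed, predicted) {
  obs <- if (is.data.frame(observed)) series_matrix(observed)$Y else observed
  obs <- as.numeric(obs)
  pred <- as.numeric(if (is.data.frame(predicted))
    series_matrix(predicted)$Y else predicted)
  if (length(obs) != length(pred))
    stop("observed and predicted must have the same length", call. = FALSE)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0)
    stop("R-squared is undefined for a constant observed series",
         call. = FALSE)
  1 - sum((obs - pred)^2) / sst
}

#' Identifiable parameter combinations
#'
#' The trajectories of the system depend on the twelve parameters only
#' through nine combinations: per tier the curvature `r/m` and the net
#' linear rate (`r_f - alpha - eta - c_f`, `r_s - beta - c_s`,
#' `r_t - c_t`), plus the three leapfrog rates, which are pinned down by the
#' inflow terms they generate in the higher tiers. Within each tier the
#' triple `(r, m, c)` is therefore only determined up to a one-parameter
#' family, and no fitting procedure can resolve all twelve parameters from
#' visit series alone. Estimates should be compared on this scale.
#'
#' @param params A [visit_params()] object.
#' @return Named numeric vector of the nine identifiable combinations.
#' @export
identifiable_combinations <- function(params) {
  validate_params(params)
  with(params, c(
    curv_f = r_f / m_f, net_f = r_f - alpha - eta - c_f,
    curv_s = r_s / m_s, net_s = r_s - beta - c_s,
    curv_t = r_t / m_t, net_t = r_t - c_t,
    alpha = alpha, beta = beta, eta = eta))
}

#' Least-squares fit of the twelve model parameters
#'
#' Minimizes the pooled sum of squared residuals between an observed
#' three-tier monthly series and the integrated model, over the twelve
#' parameters. The initial state is fixed to the first observation triple
#' (not estimated). Optimization uses bounded Levenberg--Marquardt
#' (\pkg{minpack.lm}) on the log-parameters, which enforces positivity and
#' puts all parameters on a common relative scale; the residual Jacobian is
#' obtained by finite differences. Local minima are mitigated by multiple
#' seeded starts jittered around the initial guess; the start with the
#' lowest SSE wins. The fit is deterministic given the guess, data and seed.
#'
#' Because of the structural non-identifiability described in
#' [identifiable_combinations()], the returned raw parameters are one point
#' on a ridge of equivalent optima selected by the initial guess; the nine
#' identifiable combinations are what the data actually determine.
#'
#' @param observed Observed series data frame (see [validate_series()]);
#'   at least 24 observation times.
#' @param init_guess Initial [visit_params()] guess; must lie within bounds.
#' @param bounds Optional list with elements `lower` and `upper`, each a
#'   full parameter set; defaults to `init_guess / 100` and
#'   `init_guess * 100` (zero leapfrog rates are floored at 1e-8).
#' @param n_starts Number of optimizer starts (first is the unjittered
#'   guess); default 8.
#' @param jitter_sd Standard deviation of the log-scale start jitter.
#' @param seed Seed for the start jitter; default 20220426.
#' @param weighted If `TRUE`, residuals of each tier are scaled by the
#'   inverse standard deviation of that tier's observations; default off.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return A list of class `"visit_fit"`: `params` (estimate), `sse`,
#'   `r_squared` (pooled), `per_tier_r2`, `n_obs`, `converged`,
#'   `initial_state`, `trace` (SSE per iteration of the winning start),
#'   `combos` (identifiable combinations of the estimate), `message`.
#' @export
fit_visits <- function(observed, init_guess, bounds = NULL, n_starts = 8,
                       jitter_sd = 0.05, seed = 20220426, weighted = FALSE,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, maxfev = 20000,
                         ftol = 1e-12, ptol = 1e-12, epsfcn = 1e-8)) {
  sm <- series_matrix(observed)
  if (length(sm$times) < 24L)
    stop("at least 24 observation times are required", call. = FALSE)
  validate_params(init_guess)
  g <- params_vector(init_guess)
  g[g <= 0] <- 1e-8   # log-scale needs strictly positive starts
  if (is.null(bounds)) {
    bounds <- list(lower = pmin(g / 100, g), upper = g * 100)
  } else {
    bounds <- list(lower = params_vector(bounds$lower),
                   upper = params_vector(bounds$upper))
  }
  if (any(g < bounds$lower) || any(g > bounds$upper))
    stop("init_guess must lie within bounds", call. = FALSE)

  initial <- as.numeric(sm$Y[1, ])
  w <- if (weighted) rep(1 / apply(sm$Y, 2, stats::sd), each = nrow(sm$Y)) else 1
  residual_fn <- function(logp) {
    p <- params_from_vector(exp(logp))
    pred <- tryCatch(predict_visits(p, initial, sm$times),
                     error = function(e) NULL)
    if (is.null(pred)) return(rep(1e6, length(sm$Y)))
    as.numeric(pred - sm$Y) * w
  }

  starts <- matrix(rep(log(g), n_starts), ncol = n_starts)
  if (n_starts > 1L) {
    jit <- with_seed(seed, matrix(stats::rnorm(12 * (n_starts - 1L),
                                               sd = jitter_sd),
                                  nrow = 12))
    starts[, -1L] <- starts[, -1L] + jit
    starts <- pmin(pmax(starts, log(bounds$lower)), log(bounds$upper))
  }

  best <- NULL
  for (j in seq_len(n_starts)) {
    fitj <- minpack.lm::nls.lm(par = starts[, j], fn = residual_fn,
                               lower = log(bounds$lower),
                               upper = log(bounds$upper), control = control)
    if (is.null(best) || fitj$deviance < best$deviance) best <- fitj
  }

  est <- params_from_vector(exp(best$par))
  pred <- predict_visits(est, initial, sm$times)
  per_tier <- vapply(tier_levels(),
                     function(k) r_squared(sm$Y[, k], pred[, k]), 0)
  structure(list(params = est,
                 sse = sum((pred - sm$Y)^2),
                 r_squared = r_squared(sm$Y, pred),
                 per_tier_r2 = per_tier,
                 n_obs = length(sm$Y),
                 converged = best$info %in% 1:4,
                 initial_state = initial,
                 trace = best$rsstrace,
                 combos = identifiable_combinations(est),
                 message = best$message),
            class = "visit_fit")
}

#' @export
print.visit_fit <- function(x, ...) {
  cat(sprintf("Three-tier visit model fit: %d observations, SSE = %.6g, pooled R^2 = %.4f\n",
              x$n_obs, x$sse, x$r_squared))
  cat(if (x$converged) "Converged" else "Did NOT converge", "-", x$message, "\n")
  print(x$params)
  invisible(x)
}
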