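#' Integrate the visit system over a time grid
#'
#' Numerically integrates the three-tier vector field with an adaptive
#' Runge--Kutta 4(5) scheme (Dormand--Prince, via \pkg{deSolve}). The
#' quadratic right-hand side is smooth and non-stiff at the monthly rates of
#' interest. Components that undershoot zero by no more than the solver's
#' absolute tolerance are clipped to zero; a larger undershoot raises an
#' error, since the exact flow preserves the non-negative octant.
#'
#' @param params A [visit_params()] object.
#' @param initial Numeric `c(x, y, z)`, non-negative, the state at
#'   `times[1]`.
#' @param times Strictly increasing numeric vector of output times (months).
#' @param method \pkg{deSolve} integration method; default `"ode45"`.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param compiled Use the package's C implementation of the vector field
#'   (default); set `FALSE` to integrate the R-level [visit_rhs()] instead.
#'   Both define the same field; the C path is roughly two orders of
#'   magnitude faster and is what the fitting routines exercise.
#' @return A data frame of class `"visit_trajectory"` with columns
#'   `t`, `x`, `y`, `z`.
#' @examples
#' tr <- integrate_visits(reference_params(), c(100, 100, 100), 0:60)
#' tail(tr)
#' @export
integrate_visits <- function(params, initial, times, method = "ode45",
                             rtol = 1e-8, atol = 1e-10, compiled = TRUE) {
  validate_params(params)
  validate_state(initial)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be strictly increasing with at least two points",
         call. = FALSE)
  y0 <- c(x = initial[[1]], y = initial[[2]], z = initial[[3]])
  sol <- if (compiled) {
    deSolve::ode(y = y0, times = times, func = "tierdyn_derivs",
                 parms = params_vector(params), dllname = "tierdyn",
                 initfunc = "tierdyn_initmod",
                 method = method, rtol = rtol, atol = atol)
  } else {
    deriv <- function(t, state, parms) list(visit_rhs(pmax(state, 0), parms))
    deSolve::ode(y = y0, times = times, func = deriv, parms = params,
                 method = method, rtol = rtol, atol = atol)
  }
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1L] < 0)
    stop("integration failed: ", paste(attr(sol, "istate"), collapse = " "),
         call. = FALSE)
  out <- as.data.frame(sol)
  names(out) <- c("t", "x", "y", "z")
  vals <- as.matrix(out[c("x", "y", "z")])
  if (any(vals < -100 * atol))
    stop("integration produced negative visit counts beyond solver tolerance",
         call. = FALSE)
  out[c("x", "y", "z")] <- pmax(vals, 0)
  class(out) <- c("visit_trajectory", "data.frame")
  out
}

#' @export
plot.visit_trajectory <- function(x, ...) {
  graphics::matplot(x$t, as.matrix(x[c("x", "y", "z")]), type = "l",
                    lty = 1, col = c(4, 3, 2),
                    xlab = "time (months)",
                    ylab = "visits (10,000 / month)", ...)
  graphics::legend("bottomright", legend = c("first-level", "second-level",
                                             "third-level"),
                   col = c(4, 3, 2), lty = 1, bty = "n")
  invisible(x)
}

#' Integrate to a steady state
#'
#' Integrates forward in chunks until the scaled speed
#' `||rhs(state)|| / max(m_f, m_s, m_t)` drops below `tol`, or `t_max`
#' months have elapsed. Non-convergence is signalled by the flag, not an
#' error.
#'
#' @param params A [visit_params()] object.
#' @param initial Non-negative starting state `c(x, y, z)`.
#' @param tol Relative tolerance on the scaled speed; default `1e-8`.
#' @param t_max Maximum horizon in months; default 2000.
#' @param chunk Chunk length in months between convergence checks.
#' @return A list with `state` (the final state), `converged` (logical),
#'   and `t` (the time reached).
#' @examples
#' ss <- steady_state(reference_params(), c(100, 100, 100))
#' ss$state  # approaches the positive equilibrium
#' @export
steady_state <- function(params, initial, tol = 1e-8, t_max = 2000,
                         chunk = 100) {
  validate_params(params)
  validate_state(initial)
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
  scale <- max(params$m_f, params$m_s, params$m_t)
  state <- initial
  t <- 0
  repeat {
    speed <- sqrt(sum(visit_rhs(state, params)^2)) / scale
    if (speed < tol)
      return(list(state = state, converged = TRUE, t = t))
    if (t >= t_max)
      return(list(state = state, converged = FALSE, t = t))
    step <- min(chunk, t_max - t)
    tr <- integrate_visits(params, state, c(0, step), atol = 1e-12)
    state <- unlist(tr[nrow(tr), c("x", "y", "z")])
    t <- t + step
  }
}

#' One-parameter sensitivity sweep
#'
#' Re-integrates the system for each value of a single parameter, holding
#' everything else (including the initial state and time grid) fixed. This
#' reproduces the standard sensitivity experiment: vary one leapfrog rate or
#' capacity across values below, at, and above a baseline and compare the
#' resulting visit trajectories. Because the coupling is triangular, the
#' first-tier trajectory is untouched by `beta`, `m_s`, `m_t`, `r_s`, `r_t`,
#' `c_s`, `c_t`, and the second tier is untouched by `m_t`, `r_t`, `c_t`.
#'
#' @param params Baseline [visit_params()].
#' @param name Name of the parameter to vary (one of the twelve fields).
#' @param values Numeric vector of values; each must keep the set valid.
#' @param initial Initial state shared by all runs.
#' @param times Shared output time grid (months).
#' @param ... Passed to [integrate_visits()].
#' @return A list of class `"visit_sweep"` with fields `parameter`,
#'   `values`, `baseline`, and `trajectories` (one per value).
#' @export
sweep_parameter <- function(params, name, values, initial,
                            times = seq(0, 600, by = 1), ...) {
  validate_params(params)
  if (!name %in% param_names())
    stop("unknown parameter name '", name, "'", call. = FALSE)
  if (!length(values))
    stop("'values' must be non-empty", call. = FALSE)
  trajectories <- lapply(values, function(v) {
    p <- params
    p[[name]] <- v
    validate_params(p)
    integrate_visits(p, initial, times, ...)
  })
  structure(list(parameter = name, values = values, baseline = params,
                 trajectories = trajectories),
            class = "visit_sweep")
}

#' Capacity sweep at 0.5, 1 and 1.5 times the baseline
#'
#' Convenience wrapper around [sweep_parameter()] for the capacity
#' experiments: runs the system with one tier's maximum capacity at half,
#' equal to, and one-and-a-half times its baseline value.
#'
#' @param params Baseline [visit_params()].
#' @param name One of `"m_f"`, `"m_s"`, `"m_t"`.
#' @param multipliers Multipliers applied to the baseline capacity.
#' @inheritParams sweep_parameter
#' @return A `"visit_sweep"` object.
#' @export
capacity_sweep <- function(params, name, multipliers = c(0.5, 1, 1.5),
                           initial, times = seq(0, 600, by = 1), ...) {
  name <- match.arg(name, c("m_f", "m_s", "m_t"))
  sweep_parameter(params, name, multipliers * params[[name]], initial,
                  times, ...)
}

#' Terminal states of a sweep
#'
#' @param sweep A `"visit_sweep"` object.
#' @return A matrix with one row per swept value and columns `x`, `y`, `z`.
#' @export
terminal_states <- function(sweep) {
  stopifnot(inherits(sweep, "visit_sweep"))
  out <- t(vapply(sweep$trajectories,
                  function(tr) unlist(tr[nrow(tr), c("x", "y", "z")]),
                  c(x = 0, y = 0, z = 0)))
  rownames(out) <- signif(sweep$values, 8)
  out
}
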