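#' Load-dependent growth rate of visits
#'
#' The per-visit growth rate declines linearly with the current load: it
#' equals `r` when the tier is empty and 0 when the tier is at capacity `m`,
#' i.e. `r - (r/m) * v`.
#'
#' @param v Current visit count (10,000 visits/month); may be a vector.
#' @param r Inherent growth rate at zero load (per month).
#' @param m Maximum visit capacity (10,000 visits/month); must be positive.
#' @return The growth rate(s) at load `v`.
#' @examples
#' logistic_rate(0, 0.0982, 9000.1)      # r at zero load
#' logistic_rate(9000.1, 0.0982, 9000.1) # 0 at capacity
#' @export
logistic_rate <- function(v, r, m) {
  if (any(m <= 0)) stop("capacity 'm' must be strictly positive", call. = FALSE)
  r - (r / m) * v
}

#' Vector field of the three-tier visit system
#'
#' Time derivative of the state `(x, y, z)` of monthly visits at first-,
#' second- and third-level hospitals:
#' \deqn{dx/dt = -(r_f/m_f) x^2 + r_f x - \alpha x - \eta x - c_f x}
#' \deqn{dy/dt = -(r_s/m_s) y^2 + r_s y + \alpha x - \beta y - c_s y}
#' \deqn{dz/dt = -(r_t/m_t) z^2 + r_t z + \eta x + \beta y - c_t z}
#' Each tier grows logistically toward its capacity, loses visits to churn,
#' and lower tiers feed higher tiers through the leapfrog terms. The
#' coupling is triangular: `dx/dt` depends only on `x`, and `dy/dt` only on
#' `x` and `y`, so the non-negative octant is forward invariant.
#'
#' @param state Numeric vector `c(x, y, z)` of non-negative visit counts.
#' @param params A [visit_params()] object.
#' @return Numeric vector `c(dx, dy, dz)`.
#' @examples
#' visit_rhs(c(0, 0, 0), reference_params())  # the origin is an equilibrium
#' @export
visit_rhs <- function(state, params) {
  validate_state(state)
  x <- state[[1]]; y <- state[[2]]; z <- state[[3]]
  dx <- x * (logistic_rate(x, params$r_f, params$m_f) -
               params$alpha - params$eta - params$c_f)
  dy <- y * (logistic_rate(y, params$r_s, params$m_s) -
               params$beta - params$c_s) + params$alpha * x
  dz <- z * (logistic_rate(z, params$r_t, params$m_t) -
               params$c_t) + params$eta * x + params$beta * y
  c(dx, dy, dz)
}

validate_state <- function(state) {
  if (!is.numeric(state) || length(state) != 3L || any(!is.finite(state)))
    stop("state must be a finite numeric vector c(x, y, z)", call. = FALSE)
  if (any(state < 0))
    stop("visit counts must be non-negative", call. = FALSE)
  invisible(state)
}

#' Analytic solution of the first-tier equation
#'
#' The first-tier equation decouples from the rest of the system and is a
#' scalar logistic equation with effective rate
#' `rho = r_f - alpha - eta - c_f` and carrying value `K = m_f * rho / r_f`:
#' \deqn{x(t) = \frac{x_0 e^{\rho t}}{1 + (r_f/(m_f \rho))\, x_0 (e^{\rho t} - 1)}.}
#' For `rho = 0` the separable limit `x(t) = x_0 / (1 + (r_f/m_f) x_0 t)`
#' is returned. This closed form serves as an independent oracle for the
#' numerical integrator.
#'
#' @param t Time in months (vectorized).
#' @param x0 Initial first-tier visit count at `t = 0`; non-negative.
#' @param params A [visit_params()] object.
#' @return `x(t)` at the requested times.
#' @export
closed_form_x <- function(t, x0, params) {
  validate_params(params)
  if (x0 < 0) stop("x0 must be non-negative", call. = FALSE)
  rho <- with(params, r_f - alpha - eta - c_f)
  a <- params$r_f / params$m_f
  if (rho == 0) return(x0 / (1 + a * x0 * t))
  # expm1 keeps the denominator stable for small |rho * t|
  x0 * exp(rho * t) / (1 + (a / rho) * x0 * expm1(rho * t))
}
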