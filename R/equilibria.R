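#' Existence conditions for the non-trivial equilibria
#'
#' Evaluates the three strict inequalities that govern which equilibria of
#' the system exist:
#' * `H1`: `r_t > c_t` — third-level growth exceeds churn (equilibrium with
#'   patients only at third-level hospitals);
#' * `H2`: `r_s > beta + c_s` — second-level growth exceeds its total
#'   outflow rate (equilibrium with patients at the two upper tiers);
#' * `H3`: `r_f > alpha + eta + c_f` — first-level growth exceeds its total
#'   outflow rate (positive equilibrium, all tiers occupied).
#'
#' Comparisons are strict; a difference within `tol` of zero yields `FALSE`
#' together with a marginal flag: equality is a boundary at which the
#' equilibrium merges with another, so no existence claim is made there.
#'
#' @param params A [visit_params()] object.
#' @param tol Absolute tolerance for the marginal flag; defaults to
#'   `1e-10 * max(r_f, r_s, r_t)`.
#' @return A list with logical entries `H1`, `H2`, `H3` and a logical vector
#'   `marginal` of the same names.
#' @export
existence_conditions <- function(params, tol = NULL) {
  validate_params(params)
  if (is.null(tol)) tol <- 1e-10 * max(params$r_f, params$r_s, params$r_t)
  d <- c(H1 = params$r_t - params$c_t,
         H2 = params$r_s - params$beta - params$c_s,
         H3 = params$r_f - params$alpha - params$eta - params$c_f)
  marginal <- abs(d) <= tol
  held <- d > tol
  list(H1 = unname(held["H1"]), H2 = unname(held["H2"]),
       H3 = unname(held["H3"]), marginal = marginal)
}

#' Positive root of the third-tier balance at equilibrium
#'
#' At equilibrium the third-tier count solves the quadratic
#' `-(r_t/m_t) z^2 + (r_t - c_t) z + inflow = 0`, where `inflow` is the
#' leapfrog supply `eta * x + beta * y` from the lower tiers. Its unique
#' non-negative root is
#' `z = (m_t / (2 r_t)) * ((r_t - c_t) + sqrt((r_t - c_t)^2 + 4 r_t * inflow / m_t))`.
#' With zero inflow this reduces to `max(0, m_t (r_t - c_t) / r_t)`.
#'
#' @param inflow Leapfrog inflow into the third tier (10,000 visits/month);
#'   non-negative.
#' @param params A [visit_params()] object.
#' @return The non-negative equilibrium third-tier count.
#' @export
positive_root_z <- function(inflow, params) {
  validate_params(params)
  if (inflow < 0) stop("inflow must be non-negative", call. = FALSE)
  d <- params$r_t - params$c_t
  a <- params$r_t / params$m_t
  if (inflow == 0) return(max(0, d / a))
  (d + sqrt(d^2 + 4 * a * inflow)) / (2 * a)
}

#' Closed-form equilibria of the three-tier system
#'
#' Computes one of the four equilibria:
#' * `E1` = (0, 0, 0), always present (system empty);
#' * `E2` = (0, 0, `m_t (r_t - c_t) / r_t`), present iff `H1`;
#' * `E3` = (0, `m_s (r_s - beta - c_s) / r_s`, z), present iff `H2`, with z
#'   the positive root fed by `beta * y`;
#' * `E4` = (x, y, z) with `x = m_f (r_f - alpha - eta - c_f) / r_f`,
#'   `y` the positive root of the second-tier quadratic fed by `alpha * x`,
#'   and `z` fed by `eta * x + beta * y`; present iff `H3`.
#'
#' When the governing condition fails, the raw closed form would produce a
#' negative (meaningless) coordinate, so the report carries `exists = FALSE`
#' and withholds the point (`NA` coordinates). On the condition's boundary
#' (equality within tolerance) `exists` is still `FALSE` but the `marginal`
#' flag is set and the well-defined limiting point — where the equilibrium
#' merges with a boundary equilibrium — is reported.
#'
#' @param label One of `"E1"`, `"E2"`, `"E3"`, `"E4"`.
#' @param params A [visit_params()] object.
#' @return A list of class `"equilibrium_report"` with fields `label`,
#'   `point` (named numeric `c(x, y, z)` or `NA`s), `exists`, `marginal`,
#'   and `conditions` (the `H1`--`H3` flags).
#' @export
equilibrium <- function(label, params) {
  label <- match.arg(label, c("E1", "E2", "E3", "E4"))
  validate_params(params)
  cond <- existence_conditions(params)
  pt <- c(x = NA_real_, y = NA_real_, z = NA_real_)
  exists <- FALSE
  marginal <- FALSE
  if (label == "E1") {
    pt[] <- 0
    exists <- TRUE
  } else if (label == "E2") {
    exists <- cond$H1
    marginal <- unname(cond$marginal["H1"])
    if (exists || marginal)
      pt[] <- c(0, 0, max(0, with(params, m_t * (r_t - c_t) / r_t)))
  } else if (label == "E3") {
    exists <- cond$H2
    marginal <- unname(cond$marginal["H2"])
    if (exists || marginal) {
      y <- max(0, with(params, m_s * (r_s - beta - c_s) / r_s))
      pt[] <- c(0, y, positive_root_z(params$beta * y, params))
    }
  } else {
    exists <- cond$H3
    marginal <- unname(cond$marginal["H3"])
    if (exists || marginal) {
      x <- max(0, with(params, m_f * (r_f - alpha - eta - c_f) / r_f))
      bs <- with(params, r_s - beta - c_s)
      y <- with(params,
                (m_s / (2 * r_s)) * (bs + sqrt(bs^2 + 4 * alpha * r_s * x / m_s)))
      pt[] <- c(x, max(0, y),
                positive_root_z(params$eta * x + params$beta * max(0, y), params))
    }
  }
  structure(list(label = label, point = pt, exists = exists,
                 marginal = marginal,
                 conditions = cond[c("H1", "H2", "H3")]),
            class = "equilibrium_report")
}

#' All equilibria with existence flags
#'
#' Returns the four equilibrium reports. The number of existing non-trivial
#' equilibria equals the number of `H1`--`H3` conditions that hold, ranging
#' from none (only the empty state) to all three.
#'
#' @param params A [visit_params()] object.
#' @return A named list `list(E1 = ..., E2 = ..., E3 = ..., E4 = ...)` of
#'   [equilibrium()] reports.
#' @examples
#' eq <- all_equilibria(reference_params())
#' sapply(eq, `[[`, "exists")
#' @export
all_equilibria <- function(params) {
  out <- lapply(c("E1", "E2", "E3", "E4"), equilibrium, params = params)
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("Equilibrium %s: %s%s\n", x$label,
              if (x$exists) "exists" else "does not exist",
              if (x$marginal) " (marginal: existence condition on its boundary)" else ""))
  if (x$exists)
    cat(sprintf("  point (10,000 visits/month): x = %.6g, y = %.6g, z = %.6g\n",
                x$point[["x"]], x$point[["y"]], x$point[["z"]]))
  invisible(x)
}
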