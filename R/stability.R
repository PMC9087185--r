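#' Jacobian of the visit system
#'
#' The Jacobian of the vector field at a state `(x, y, z)` is lower
#' triangular, reflecting the one-way flow of patients up the tiers:
#' diagonal entries
#' `(-2 r_f x / m_f + r_f - alpha - eta - c_f,
#'   -2 r_s y / m_s + r_s - beta - c_s,
#'   -2 r_t z / m_t + r_t - c_t)`,
#' sub-diagonal entries `alpha` (2,1), `eta` (3,1), `beta` (3,2), and zeros
#' above the diagonal. Its eigenvalues are therefore the (real) diagonal
#' entries.
#'
#' @param state Numeric vector `c(x, y, z)`.
#' @param params A [visit_params()] object.
#' @return A 3x3 numeric matrix.
#' @export
visit_jacobian <- function(state, params) {
  validate_state(state)
  validate_params(params)
  x <- state[[1]]; y <- state[[2]]; z <- state[[3]]
  a11 <- with(params, -2 * r_f * x / m_f + r_f - alpha - eta - c_f)
  a22 <- with(params, -2 * r_s * y / m_s + r_s - beta - c_s)
  a33 <- with(params, -2 * r_t * z / m_t + r_t - c_t)
  matrix(c(a11,          0,   0,
           params$alpha, a22, 0,
           params$eta,   params$beta, a33),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
}

#' Eigenvalues of the Jacobian at an equilibrium
#'
#' Because the Jacobian is lower triangular its eigenvalues are the diagonal
#' entries, evaluated here at the closed-form equilibrium point. At the
#' origin they are `(r_f - alpha - eta - c_f, r_s - beta - c_s, r_t - c_t)`;
#' at an occupied tier the quadratic balance flips the corresponding entry
#' to a negative square-root discriminant.
#'
#' @param label One of `"E1"`, `"E2"`, `"E3"`, `"E4"`.
#' @param params A [visit_params()] object.
#' @return Numeric vector of the three (real) eigenvalues.
#' @export
eigenvalues_at <- function(label, params) {
  eq <- equilibrium(label, params)
  if (!eq$exists && !eq$marginal)
    stop("equilibrium ", label, " does not exist for these parameters",
         call. = FALSE)
  diag(visit_jacobian(eq$point, params))
}

stability_flags <- function(params) {
  bf <- with(params, r_f - alpha - eta - c_f)
  bs <- with(params, r_s - beta - c_s)
  bt <- with(params, r_t - c_t)
  list(H4 = bf < 0 && bs < 0 && bt < 0,
       H5 = bf < 0 && bs < 0 && bt > 0,
       H6 = bf < 0 && bs > 0,
       H7 = bf > 0)
}

#' Local stability classification of an equilibrium
#'
#' Classifies the labelled equilibrium from the signs of its Jacobian
#' eigenvalues: `stable` when all are negative, `unstable` when some are
#' positive, and `marginal` when the largest is zero within tolerance (a
#' non-hyperbolic point, for which the linearization is silent). The report
#' also carries the four parameter-regime flags:
#' * `H4`: all three net rates negative — the empty state attracts;
#' * `H5`: first and second net rates negative, `r_t > c_t` — only the
#'   third tier persists;
#' * `H6`: first net rate negative, `r_s > beta + c_s` — the two upper
#'   tiers persist;
#' * `H7`: `r_f > alpha + eta + c_f` — the positive equilibrium attracts.
#'
#' These four regimes partition parameter space (off their boundaries), and
#' each implies stability of the corresponding equilibrium; the function
#' checks that implication against the computed eigenvalues.
#'
#' @param label One of `"E1"`, `"E2"`, `"E3"`, `"E4"`.
#' @param params A [visit_params()] object.
#' @param tol Eigenvalues within `tol` of zero are treated as zero;
#'   defaults to `1e-10 * max(r_f, r_s, r_t)`.
#' @return A list of class `"stability_report"` with fields `label`,
#'   `eigenvalues`, `classification`, and `conditions` (`H4`--`H7` flags).
#' @examples
#' classify_equilibrium("E4", reference_params())
#' @export
classify_equilibrium <- function(label, params, tol = NULL) {
  validate_params(params)
  if (is.null(tol)) tol <- 1e-10 * max(params$r_f, params$r_s, params$r_t)
  ev <- eigenvalues_at(label, params)
  cls <- if (max(ev) < -tol) "stable"
         else if (max(ev) > tol) "unstable"
         else "marginal"
  flags <- stability_flags(params)
  guarantee <- switch(label, E1 = "H4", E2 = "H5", E3 = "H6", E4 = "H7")
  if (isTRUE(flags[[guarantee]]) && cls == "unstable")
    warning("eigenvalue classification contradicts condition ", guarantee,
            "; parameters may sit on a degeneracy", call. = FALSE)
  structure(list(label = label, eigenvalues = ev, classification = cls,
                 conditions = flags),
            class = "stability_report")
}

#' Stability summary over all existing equilibria
#'
#' Classifies every equilibrium that exists for the given parameters. Away
#' from the boundary hypersurfaces exactly one equilibrium is stable, and
#' which one is dictated by the `H4`--`H7` regime.
#'
#' @param params A [visit_params()] object.
#' @return A list with `reports` (one [classify_equilibrium()] report per
#'   existing equilibrium) and `stable` (the label(s) classified stable).
#' @export
stability_summary <- function(params) {
  eq <- all_equilibria(params)
  labels <- names(eq)[vapply(eq, `[[`, TRUE, "exists")]
  reports <- lapply(labels, classify_equilibrium, params = params)
  names(reports) <- labels
  stable <- labels[vapply(reports, function(r) r$classification == "stable",
                          TRUE)]
  list(reports = reports, stable = stable)
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Equilibrium %s: %s\n  eigenvalues: %s\n", x$label,
              x$classification,
              paste(signif(x$eigenvalues, 6), collapse = ", ")))
  invisible(x)
}
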