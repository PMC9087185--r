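#' Model parameters for the three-tier visit system
#'
#' Constructs and validates the twelve parameters of the visit-dynamics
#' model. Time is measured in months and visit counts in units of 10,000
#' visits per month, matching the scale of national monthly series.
#'
#' @param r_f,r_s,r_t Inherent growth rates of visits at first-, second- and
#'   third-level hospitals (per month); strictly positive.
#' @param m_f,m_s,m_t Maximum visit capacities per tier (10,000 visits/month);
#'   strictly positive. The growth rate declines linearly from `r` at zero
#'   load to 0 at capacity.
#' @param c_f,c_s,c_t Churn rates per tier (per month): fractional loss of
#'   visits to deaths and abandoned treatment; strictly positive.
#' @param alpha Leapfrog rate from first- to second-level hospitals
#'   (per month); non-negative.
#' @param beta Leapfrog rate from second- to third-level hospitals
#'   (per month); non-negative.
#' @param eta Leapfrog rate from first- to third-level hospitals
#'   (per month); non-negative.
#'
#' @details The leapfrog rates are admitted at exactly zero (the model is
#'   usually stated with strictly positive transfer) so that decoupled
#'   single-tier behaviour is expressible, e.g. in oracle tests.
#'
#' @return A named list of class `"visit_params"`.
#' @examples
#' p <- visit_params(r_f = 0.1, r_s = 0.1, r_t = 0.05,
#'                   m_f = 100, m_s = 200, m_t = 300,
#'                   c_f = 0.01, c_s = 0.02, c_t = 0.03,
#'                   alpha = 0.02, beta = 0.01, eta = 0.005)
#' @export
visit_params <- function(r_f, r_s, r_t, m_f, m_s, m_t,
                         c_f, c_s, c_t, alpha, beta, eta) {
  p <- list(r_f = r_f, r_s = r_s, r_t = r_t,
            m_f = m_f, m_s = m_s, m_t = m_t,
            c_f = c_f, c_s = c_s, c_t = c_t,
            alpha = alpha, beta = beta, eta = eta)
  validate_params(p)
  structure(p, class = "visit_params")
}

#' @rdname visit_params
#' @param p An object to validate as a parameter set.
#' @export
validate_params <- function(p) {
  need <- param_names()
  if (!is.list(p) || !setequal(names(p), need))
    stop("parameter set must have exactly the fields: ",
         paste(need, collapse = ", "), call. = FALSE)
  for (nm in need) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  pos <- c("r_f", "r_s", "r_t", "m_f", "m_s", "m_t", "c_f", "c_s", "c_t")
  for (nm in pos)
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  for (nm in c("alpha", "beta", "eta"))
    if (p[[nm]] < 0)
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  invisible(p)
}

param_names <- function() {
  c("r_f", "r_s", "r_t", "m_f", "m_s", "m_t",
    "c_f", "c_s", "c_t", "alpha", "beta", "eta")
}

#' Reference parameter set estimated from China's national monthly series
#'
#' The parameter values obtained by least-squares fitting of the model to
#' national monthly visit counts of the three hospital tiers (January to
#' November of 2011--2018, in units of 10,000 visits/month). Under these
#' values the system has a locally stable positive equilibrium: all three
#' tiers retain patients in the long run, while third-level growth is below
#' churn (`r_t < c_t`), so third-level visits are sustained by leapfrog
#' inflow alone.
#'
#' @return A `"visit_params"` object.
#' @seealso [all_equilibria()], [stability_summary()]
#' @export
reference_params <- function() {
  visit_params(r_f = 0.0982, r_s = 0.1096, r_t = 0.0020,
               m_f = 9000.1, m_s = 29899.2, m_t = 42999.8,
               c_f = 0.0010, c_s = 0.0406, c_t = 0.0271,
               alpha = 0.044, beta = 0.037, eta = 0.030)
}

#' @export
print.visit_params <- function(x, ...) {
  cat("Three-tier visit model parameters (per month; capacities in 10,000 visits):\n")
  v <- unlist(x)
  print(v, ...)
  invisible(x)
}

#' Convert a parameter set to a plain named numeric vector
#' @param p A `"visit_params"` object.
#' @return Named numeric vector of length 12.
#' @export
params_vector <- function(p) {
  validate_params(p)
  unlist(p[param_names()])
}

params_from_vector <- function(v) {
  if (is.null(names(v))) names(v) <- param_names()
  do.call(visit_params, as.list(v[param_names()]))
}

#' Read and write parameter sets as JSON
#'
#' The JSON document must contain exactly the twelve parameter fields;
#' unknown keys are rejected. Values are serialized at full precision so a
#' write/read round trip is exact.
#'
#' @param path Path of the JSON file.
#' @return `read_params_json()` returns a `"visit_params"` object;
#'   `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw))
    stop("parameter file must be a JSON object", call. = FALSE)
  as_visit_params(raw)
}

# Build a visit_params from a plain named list, rejecting unknown or
# missing fields with a clear message (unlike do.call on the constructor).
as_visit_params <- function(lst) {
  extra <- setdiff(names(lst), param_names())
  if (length(extra))
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(param_names(), names(lst))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(visit_params, lst[param_names()])
}

#' @rdname read_params_json
#' @param p A `"visit_params"` object to write.
#' @export
write_params_json <- function(p, path) {
  validate_params(p)
  jsonlite::write_json(p[param_names()], path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}
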