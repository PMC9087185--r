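# Shared fixtures for the test suite.

ref <- reference_params()

# Multiply every parameter of a set by a common factor.
scale_params <- function(p, factor) {
  do.call(visit_params, lapply(unclass(p), function(v) factor * v))
}

# Modify selected fields of a parameter set.
tweak_params <- function(p, ...) {
  mods <- list(...)
  q <- unclass(p)
  q[names(mods)] <- mods
  do.call(visit_params, q)
}

# A parameter set in the all-decline regime (H4): every equilibrium but the
# origin fails to exist and the origin attracts.
decline_params <- visit_params(
  r_f = 0.02, r_s = 0.02, r_t = 0.02,
  m_f = 100, m_s = 200, m_t = 300,
  c_f = 0.05, c_s = 0.05, c_t = 0.05,
  alpha = 0.01, beta = 0.01, eta = 0.01)

# A well-conditioned positive-equilibrium set (H1, H2, H3 all hold) with
# appreciable curvature in every tier, used where the fit or the dynamics
# must be numerically well determined.
strong_params <- visit_params(
  r_f = 0.25, r_s = 0.2, r_t = 0.15,
  m_f = 500, m_s = 800, m_t = 1200,
  c_f = 0.02, c_s = 0.03, c_t = 0.02,
  alpha = 0.03, beta = 0.02, eta = 0.01)

max_rel_err <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-12))
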