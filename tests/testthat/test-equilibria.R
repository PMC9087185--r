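test_that("existence conditions compare growth against total outflow", {
  cond <- existence_conditions(ref)
  expect_false(cond$H1)   # 0.0020 < 0.0271
  expect_true(cond$H2)    # 0.1096 > 0.037 + 0.0406
  expect_true(cond$H3)    # 0.0982 > 0.044 + 0.030 + 0.0010
  expect_false(any(cond$marginal))

  # equality is a boundary: condition false, marginal flagged
  m <- existence_conditions(tweak_params(ref, r_t = ref$c_t))
  expect_false(m$H1)
  expect_true(m$marginal[["H1"]])

  # strong growth, weak losses: everything exists
  all3 <- existence_conditions(strong_params)
  expect_true(all3$H1 && all3$H2 && all3$H3)
})

test_that("the third-tier-only equilibrium follows the logistic balance", {
  p <- visit_params(r_f = 0.1, r_s = 0.1, r_t = 0.2,
                    m_f = 100, m_s = 100, m_t = 100,
                    c_f = 0.01, c_s = 0.01, c_t = 0.1,
                    alpha = 0.01, beta = 0.01, eta = 0.01)
  e2 <- equilibrium("E2", p)
  expect_true(e2$exists)
  expect_equal(unname(e2$point), c(0, 0, 50))   # m_t (r_t - c_t) / r_t

  # c_t -> 0 pushes the point to capacity
  e2b <- equilibrium("E2", tweak_params(p, c_t = 1e-9))
  expect_equal(e2b$point[["z"]], 100, tolerance = 1e-7)

  # reference parameters violate H1: no point reported
  e2c <- equilibrium("E2", ref)
  expect_false(e2c$exists)
  expect_true(all(is.na(e2c$point)))
})

test_that("upper-two-tier equilibrium matches its closed form", {
  e3 <- equilibrium("E3", ref)
  expect_true(e3$exists)
  y_expect <- 29899.2 * (0.1096 - 0.037 - 0.0406) / 0.1096
  expect_equal(e3$point[["x"]], 0)
  expect_equal(e3$point[["y"]], y_expect, tolerance = 1e-12)

  # beta = 0 decouples the second tier and starves the third of inflow
  p <- tweak_params(strong_params, beta = 0)
  e3b <- equilibrium("E3", p)
  expect_equal(e3b$point[["y"]], with(p, m_s * (r_s - c_s) / r_s))
  expect_equal(e3b$point[["z"]], positive_root_z(0, p))

  # boundary r_s = beta + c_s: marginal, not existing
  pb <- tweak_params(ref, r_s = ref$beta + ref$c_s)
  e3c <- equilibrium("E3", pb)
  expect_false(e3c$exists)
  expect_true(e3c$marginal)
})

test_that("positive-root solver for the third tier handles all regimes", {
  expect_equal(positive_root_z(0, strong_params),
               with(strong_params, m_t * (r_t - c_t) / r_t))
  expect_equal(positive_root_z(0, ref), 0)  # r_t < c_t: only root is 0

  # cross-check the quadratic formula against a numeric root-finder
  inflow <- 472.3
  z <- positive_root_z(inflow, ref)
  f <- function(zz) with(ref, -(r_t / m_t) * zz^2 + (r_t - c_t) * zz + inflow)
  z_numeric <- uniroot(f, c(1, 1e6), tol = 1e-10)$root
  expect_equal(z, z_numeric, tolerance = 1e-8)
  expect_equal(f(z), 0, tolerance = 1e-8)
})

test_that("positive equilibrium matches closed form, including the national fit", {
  # three decoupled logistic-with-loss tiers
  p <- visit_params(r_f = 0.1, r_s = 0.1, r_t = 0.1,
                    m_f = 100, m_s = 100, m_t = 100,
                    c_f = 0.05, c_s = 0.05, c_t = 0.05,
                    alpha = 0, beta = 0, eta = 0)
  expect_equal(unname(equilibrium("E4", p)$point), c(50, 50, 50))

  # reference parameters: evaluate the closed forms independently
  x4 <- 9000.1 * (0.0982 - 0.044 - 0.030 - 0.0010) / 0.0982
  bs <- 0.1096 - 0.037 - 0.0406
  y4 <- (29899.2 / (2 * 0.1096)) *
    (bs + sqrt(bs^2 + 4 * 0.044 * 0.1096 * x4 / 29899.2))
  z4 <- positive_root_z(0.030 * x4 + 0.037 * y4, ref)
  e4 <- equilibrium("E4", ref)
  expect_true(e4$exists)
  expect_equal(unname(e4$point), c(x4, y4, z4), tolerance = 1e-12)
  # the magnitudes themselves (10,000 visits/month)
  expect_equal(unname(e4$point), c(2126.3, 11041.3, 18203.3), tolerance = 1e-4)

  # transfer rates -> 0 reduces x to the decoupled logistic-with-loss value
  p0 <- tweak_params(ref, alpha = 1e-12, eta = 1e-12)
  expect_equal(equilibrium("E4", p0)$point[["x"]],
               with(ref, m_f * (r_f - c_f) / r_f), tolerance = 1e-9)
})

test_that("the census of equilibria follows the three conditions", {
  counts <- function(p) sum(vapply(all_equilibria(p), `[[`, TRUE, "exists"))
  expect_equal(counts(strong_params), 4)  # all of H1, H2, H3
  expect_equal(counts(ref), 3)            # H2 and H3 only
  expect_equal(counts(decline_params), 1) # none hold: only the empty state
  eq <- all_equilibria(ref)
  expect_false(eq$E2$exists)
  expect_true(eq$E3$exists && eq$E4$exists)
})

test_that("every reported equilibrium is a zero of the field, and x4 responds
           only to the parameters that enter the first tier", {
  for (s in 1:20) {
    p <- random_params(seed = 500 + s)
    for (e in all_equilibria(p)) {
      if (!e$exists) next
      expect_lt(sqrt(sum(visit_rhs(e$point, p)^2)) /
                  max(p$m_f, p$m_s, p$m_t), 1e-8)
    }
  }
  # monotone decrease in alpha and eta; invariance to beta, m_s, m_t
  x4 <- function(p) equilibrium("E4", p)$point[["x"]]
  base <- x4(ref)
  expect_lt(x4(tweak_params(ref, alpha = 0.05)), base)
  expect_lt(x4(tweak_params(ref, eta = 0.04)), base)
  expect_identical(x4(tweak_params(ref, beta = 0.9)), base)
  expect_identical(x4(tweak_params(ref, m_s = 1e5, m_t = 7)), base)
})

test_that("closed-form equilibria agree with long-time integration", {
  hits <- 0
  s <- 0
  while (hits < 10 && s < 60) {
    s <- s + 1
    p <- random_params(seed = 700 + s)
    st <- stability_summary(p)
    if (length(st$stable) != 1) next
    eig <- st$reports[[st$stable]]$eigenvalues
    if (max(eig) > -5e-3) next  # skip nearly non-hyperbolic draws
    hits <- hits + 1
    target <- equilibrium(st$stable, p)$point
    start <- pmax(target * 1.05, 0.02 * c(p$m_f, p$m_s, p$m_t))
    ss <- steady_state(p, start, tol = 1e-10, t_max = 6000)
    expect_true(ss$converged)
    scale <- max(target, 0.01 * max(p$m_f, p$m_s, p$m_t))
    expect_lt(max(abs(ss$state - target)) / scale, 1e-4)
  }
  expect_equal(hits, 10)
})
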