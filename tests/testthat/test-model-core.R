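test_that("the load-dependent growth rate is linear between r and 0", {
  expect_equal(logistic_rate(0, 0.0982, 9000.1), 0.0982)
  expect_equal(logistic_rate(9000.1, 0.0982, 9000.1), 0)
  expect_equal(logistic_rate(50, 0.3, 100), 0.15)
  expect_error(logistic_rate(1, 0.1, 0), "positive")
  expect_error(logistic_rate(1, 0.1, -5), "positive")
})

test_that("the vector field matches direct arithmetic on the model terms", {
  expect_equal(visit_rhs(c(0, 0, 0), ref), c(0, 0, 0))
  # logistic terms cancel at x = m_f; outflow -(alpha+eta+c_f)x; inflows
  # alpha*x and eta*x
  p <- visit_params(r_f = 0.1, r_s = 0.15, r_t = 0.05,
                    m_f = 100, m_s = 300, m_t = 400,
                    c_f = 0.01, c_s = 0.02, c_t = 0.03,
                    alpha = 0.02, beta = 0.015, eta = 0.01)
  expect_equal(visit_rhs(c(100, 0, 0), p), c(-4, 2, 1))
  expect_error(visit_rhs(c(-1, 0, 0), p), "non-negative")
})

test_that("the positive equilibrium is a zero of the vector field", {
  for (s in 1:10) {
    p <- random_params(seed = 100 + s)
    e4 <- equilibrium("E4", p)
    if (!e4$exists) next
    resid <- visit_rhs(e4$point, p)
    expect_lt(max(abs(resid)) / max(p$m_f, p$m_s, p$m_t), 1e-9)
  }
})

test_that("the non-negative octant is forward invariant at its faces", {
  for (s in 1:10) {
    p <- random_params(seed = 200 + s)
    xy <- runif(2, 0, 50)
    expect_identical(visit_rhs(c(0, xy[1], xy[2]), p)[1], 0)
    dy <- visit_rhs(c(xy[1], 0, xy[2]), p)[2]
    expect_equal(dy, p$alpha * xy[1])
    expect_gte(dy, 0)
    dz <- visit_rhs(c(xy[1], xy[2], 0), p)[3]
    expect_equal(dz, p$eta * xy[1] + p$beta * xy[2])
    expect_gte(dz, 0)
  }
})

test_that("the coupling is triangular: lower tiers ignore higher tiers", {
  for (s in 1:5) {
    p <- random_params(seed = 300 + s)
    base <- c(30, 40, 50)
    d0 <- visit_rhs(base, p)
    d1 <- visit_rhs(base + c(0, 17, -23), p)
    expect_identical(d1[1], d0[1])              # dx ignores y and z
    d2 <- visit_rhs(base + c(0, 0, 31), p)
    expect_identical(d2[1:2], d0[1:2])          # dy also ignores z
  }
})

test_that("closed-form first-tier solution has the logistic properties", {
  expect_equal(closed_form_x(0, 10, ref), 10)
  # effective carrying value K = m_f * rho / r_f is a fixed point
  rho <- with(ref, r_f - alpha - eta - c_f)
  K <- ref$m_f * rho / ref$r_f
  expect_equal(closed_form_x(c(1, 50, 500), K, ref), rep(K, 3))
  # long-time limit is K when rho > 0 (here transfer/churn nearly zero)
  p <- visit_params(r_f = 0.1, r_s = 0.1, r_t = 0.1,
                    m_f = 100, m_s = 100, m_t = 100,
                    c_f = 1e-9, c_s = 0.01, c_t = 0.01,
                    alpha = 0, beta = 0, eta = 0)
  expect_equal(closed_form_x(2000, 10, p), 100, tolerance = 1e-6)
  expect_error(closed_form_x(1, -2, ref), "non-negative")
})

test_that("the degenerate zero-net-rate case follows the separable solution", {
  # r_f exactly balances alpha + eta + c_f
  p <- visit_params(r_f = 0.1, r_s = 0.1, r_t = 0.1,
                    m_f = 100, m_s = 100, m_t = 100,
                    c_f = 0.03, c_s = 0.01, c_t = 0.01,
                    alpha = 0.04, beta = 0.01, eta = 0.03)
  expect_equal(with(p, r_f - alpha - eta - c_f), 0)
  t <- seq(0, 200, by = 5)
  expect_equal(closed_form_x(t, 20, p), 20 / (1 + 0.001 * 20 * t))
  tr <- integrate_visits(p, c(20, 10, 10), t, atol = 1e-12)
  expect_equal(tr$x, closed_form_x(t, 20, p), tolerance = 1e-7)
})

test_that("numerical integration of x agrees with the analytic oracle", {
  t <- seq(0, 200, by = 2)
  for (s in 1:5) {
    p <- random_params(seed = 400 + s)
    x0 <- 0.3 * p$m_f
    tr <- integrate_visits(p, c(x0, 10, 10), t, atol = 1e-14)
    exact <- closed_form_x(t, x0, p)
    expect_lt(max(abs(tr$x - exact) / pmax(exact, 1e-8 * x0)), 1e-6)
  }
})
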