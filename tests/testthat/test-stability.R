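test_that("the Jacobian is lower triangular and matches finite differences", {
  J <- visit_jacobian(c(0, 0, 0), ref)
  expect_equal(diag(J), c(x = 0.0232, y = 0.0320, z = -0.0251))
  expect_true(all(J[upper.tri(J)] == 0))
  expect_equal(J[2, 1], ref$alpha)
  expect_equal(J[3, 1], ref$eta)
  expect_equal(J[3, 2], ref$beta)

  # central differences of the vector field at random interior states
  for (s in 1:10) {
    p <- random_params(seed = 800 + s)
    state <- runif(3, 1, 0.8 * c(p$m_f, p$m_s, p$m_t))
    J <- visit_jacobian(state, p)
    h <- 1e-4 * pmax(state, 1)
    Jfd <- sapply(1:3, function(j) {
      e <- numeric(3); e[j] <- h[j]
      (visit_rhs(state + e, p) - visit_rhs(state - e, p)) / (2 * h[j])
    })
    expect_equal(unname(J), Jfd, tolerance = 1e-6)
  }
})

test_that("analytic eigenvalues equal a numeric eigensolver's at every equilibrium", {
  for (s in 1:50) {
    p <- random_params(seed = 900 + s)
    for (e in all_equilibria(p)) {
      if (!e$exists) next
      ev <- eigenvalues_at(e$label, p)
      ev_num <- eigen(visit_jacobian(e$point, p), only.values = TRUE)$values
      expect_true(all(abs(Im(ev_num)) == 0))
      expect_equal(sort(unname(ev)), sort(Re(ev_num)), tolerance = 1e-8)
    }
  }
})

test_that("eigenvalues at the boundary equilibria take their closed forms", {
  # third-tier-only point: the z-direction flips sign to c_t - r_t
  p <- tweak_params(strong_params, alpha = 0.3, eta = 0.2, beta = 0.25)
  expect_true(equilibrium("E2", p)$exists)
  ev <- eigenvalues_at("E2", p)
  expect_equal(ev[["z"]], p$c_t - p$r_t)
  expect_lt(ev[["z"]], 0)

  # positive equilibrium: y-direction eigenvalue is the negated discriminant
  for (s in 1:10) {
    q <- random_params(seed = 1000 + s)
    e4 <- equilibrium("E4", q)
    if (!e4$exists) next
    bs <- with(q, r_s - beta - c_s)
    expect_equal(eigenvalues_at("E4", q)[["y"]],
                 -sqrt(bs^2 + 4 * q$alpha * q$r_s * e4$point[["x"]] / q$m_s),
                 tolerance = 1e-10)
  }

  expect_error(eigenvalues_at("E2", ref), "does not exist")
})

test_that("classification follows the eigenvalue signs and the regime flags", {
  rep4 <- classify_equilibrium("E4", ref)
  expect_equal(rep4$classification, "stable")
  expect_true(rep4$conditions$H7)      # 0.0982 > 0.0750
  expect_equal(classify_equilibrium("E1", ref)$classification, "unstable")

  rep1 <- classify_equilibrium("E1", decline_params)
  expect_equal(rep1$classification, "stable")
  expect_true(rep1$conditions$H4)

  # zero net first-tier rate: non-hyperbolic, no stability claim
  pm <- tweak_params(ref, r_f = ref$alpha + ref$eta + ref$c_f)
  expect_equal(classify_equilibrium("E4", pm)$classification, "marginal")
})

test_that("exactly one equilibrium is stable off the regime boundaries", {
  for (s in 1:25) {
    p <- random_params(seed = 1100 + s)
    st <- stability_summary(p)
    expect_length(st$stable, 1)
    flags <- st$reports[[1]]$conditions
    expect_equal(sum(unlist(flags)), 1)
    expected <- c(H4 = "E1", H5 = "E2", H6 = "E3", H7 = "E4")
    expect_equal(unname(expected[names(which(unlist(flags)))]), st$stable)
  }
})

test_that("unstable equilibria are escaped along a positive eigen-direction", {
  for (s in 1:5) {
    p <- random_params(seed = 1200 + s)
    st <- stability_summary(p)
    for (r in st$reports) {
      if (r$classification != "unstable") next
      if (max(r$eigenvalues) < 0.01) next  # too slow to escape visibly
      e <- equilibrium(r$label, p)
      j <- which.max(r$eigenvalues)
      d0 <- numeric(3)
      d0[j] <- 0.01 * max(e$point[j], 0.01 * c(p$m_f, p$m_s, p$m_t)[j])
      tr <- integrate_visits(p, e$point + d0, c(0, 100, 200))
      dist <- sqrt(rowSums((as.matrix(tr[, 2:4]) -
                              matrix(e$point, 3, 3, byrow = TRUE))^2))
      expect_gt(dist[3], 2 * sqrt(sum(d0^2)))
    }
  }
})
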