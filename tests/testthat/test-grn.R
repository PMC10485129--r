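test_that("parameter construction validates and converts energy scales", {
  p <- defaultParams()
  expect_s4_class(p, "ModelParams")
  # eta <-> delta_eps round trip is exact to floating tolerance
  de <- runif(20, -8, 3)
  expect_equal(deltaEpsFromEta(etaFromDeltaEps(de)), de, tolerance = 1e-12)
  p2 <- modelParams(r_u = 0.1, r_v = 0.1, gamma_u = 1, gamma_v = 1,
                    delta_eps_u = -6.935, delta_eps_v = -6,
                    eta_s = 5, eta_vs = 11)
  expect_equal(p2@eta_u, exp(6.935))
  expect_error(modelParams(r_u = -1, r_v = 0.1, gamma_u = 1, gamma_v = 1,
                           eta_u = 2, eta_v = 2, eta_s = 1, eta_vs = 1),
               "positive")
  expect_error(modelParams(r_u = 0.1, r_v = 0.1, gamma_u = 1, gamma_v = 1,
                           eta_u = 2, eta_v = 2, eta_s = 1, eta_vs = 0.5),
               "eta_vs")
  expect_error(modelParams(r_u = 0.1, r_v = 0.1, gamma_u = 1, gamma_v = 1,
                           eta_u = 2, delta_eps_u = -1, eta_v = 2,
                           eta_s = 1, eta_vs = 1), "only one")
})

test_that("binding probabilities match the Boltzmann term-enumeration oracle", {
  set.seed(101)
  for (rep in 1:25) {
    p <- modelParams(r_u = 0.1, r_v = 0.1, gamma_u = 1, gamma_v = 1,
                     eta_u = runif(1, 0.5, 500), eta_v = runif(1, 0.5, 500),
                     eta_s = runif(1, 0.5, 20), eta_vs = runif(1, 1, 20),
                     eta_uv = sample(c(0, runif(1, 0, 2)), 1),
                     eta_us = sample(c(0, runif(1, 0, 2)), 1),
                     eta_uvs = sample(c(0, runif(1, 0, 2)), 1))
    u <- runif(1); v <- runif(1); s <- runif(1)
    got <- bindingProbabilities(u, v, s, p)
    want <- oracle_binding(u, v, s, p)
    expect_equal(got$p_u, want$p_u, tolerance = 1e-12)
    expect_equal(got$p_v, want$p_v, tolerance = 1e-12)
  }
})

test_that("binding probability reductions and edge cases hold", {
  p <- defaultParams()
  # u = 0 silences the u promoter entirely
  expect_equal(bindingProbabilities(0, 0.3, 0.2, p)$p_u, 0)
  # no-interaction factorization: s = 0, eta_uv = 1 collapses to the
  # single-species occupancy eta_u u / (1 + eta_u u)
  p1 <- modelParams(r_u = 0.1, r_v = 0.1, gamma_u = 1, gamma_v = 1,
                    eta_u = 7, eta_v = 3, eta_s = 2, eta_vs = 1.5,
                    eta_uv = 1)
  u <- 0.37; v <- 0.81
  expect_equal(bindingProbabilities(u, v, 0, p1)$p_u,
               7 * u / (1 + 7 * u), tolerance = 1e-12)
  # specialized model equals the blocking-inhibition closed forms
  u <- 0.04; v <- 0.07; s <- 0.05
  got <- bindingProbabilities(u, v, s, p)
  den <- 1 + p@eta_v * v * (1 + p@eta_s * p@eta_vs * s) + p@eta_u * u +
    p@eta_s * s
  expect_equal(got$p_u, p@eta_u * u / den, tolerance = 1e-12)
  expect_equal(got$p_v,
               p@eta_v * v * (1 + p@eta_s * p@eta_vs * s) / den,
               tolerance = 1e-12)
  expect_error(bindingProbabilities(-0.1, 0, 0, p), "nonnegative")
})

test_that("probabilities stay in the simplex and respond to the signal", {
  p <- defaultParams()
  set.seed(5)
  u <- runif(200, 0, 2); v <- runif(200, 0, 2); s <- runif(200, 0, 2)
  pr <- bindingProbabilities(u, v, s, p)
  expect_true(all(pr$p_u >= 0 & pr$p_u <= 1))
  expect_true(all(pr$p_v >= 0 & pr$p_v <= 1))
  expect_true(all(pr$p_u + pr$p_v <= 1 + 1e-12))
  # signal inhibits u and activates v at fixed (u, v)
  sgrid <- seq(0, 0.5, length.out = 40)
  pu <- bindingProbabilities(0.05, 0.05, sgrid, p)$p_u
  pv <- bindingProbabilities(0.05, 0.05, sgrid, p)$p_v
  expect_true(all(diff(pu) <= 1e-15))
  expect_true(all(diff(pv) >= -1e-15))
})

test_that("right-hand side vanishes at the closed-form steady states", {
  p <- defaultParams()
  n <- 4
  z <- rep(0, n)
  r0 <- grnRHS(z, z, runif(n), p)
  expect_equal(r0$du, z)
  expect_equal(r0$dv, z)
  s <- c(0, 0.01, 0.02, 0.05)
  uplus <- p@r_u / p@gamma_u - (1 + p@eta_s * s) / p@eta_u
  r1 <- grnRHS(uplus, z, s, p)
  expect_equal(r1$du, z, tolerance = 1e-12)
  expect_equal(r1$dv, z, tolerance = 1e-12)
  expect_error(grnRHS(1:3, 1:2, 1:3, p), "same length")
})

test_that("rhs agrees with direct evaluation of the occupancy formulas", {
  p <- defaultParams()
  set.seed(7)
  u <- runif(6, 0, 0.1); v <- runif(6, 0, 0.1); s <- runif(6, 0, 0.1)
  r <- grnRHS(u, v, s, p)
  for (i in 1:6) {
    o <- oracle_binding(u[i], v[i], s[i], p)
    expect_equal(r$du[i], p@r_u * o$p_u - p@gamma_u * u[i], tolerance = 1e-12)
    expect_equal(r$dv[i], p@r_v * o$p_v - p@gamma_v * v[i], tolerance = 1e-12)
  }
})

test_that("critical signal follows the closed form and switches the fate", {
  # numerator zero
  p0 <- modelParams(r_u = 1, r_v = 1, gamma_u = 1, gamma_v = 1,
                    eta_u = 4, eta_v = 4, eta_s = 1, eta_vs = 1)
  expect_equal(criticalSignal(p0), 0)
  # all rates 1, eta_u = 2 eta_v, eta_s*eta_vs = 1 -> s* = 1
  p1 <- modelParams(r_u = 1, r_v = 1, gamma_u = 1, gamma_v = 1,
                    eta_u = 8, eta_v = 4, eta_s = 1, eta_vs = 1)
  expect_equal(criticalSignal(p1), 1)
  # fate on either side of s*: below -> u+v-, above -> u-v+
  p <- defaultParams()
  s_star <- criticalSignal(p)
  lo <- single_cell_fate(p, s_star * 0.9)
  hi <- single_cell_fate(p, s_star * 1.1)
  expect_gt(lo[["u"]], 10 * lo[["v"]])
  expect_gt(hi[["v"]], 10 * hi[["u"]])
})

test_that("steady states report branches, degeneracy and absences", {
  p <- defaultParams()
  st0 <- steadyStates(p, 0)
  expect_equal(st0$u_pos[["u"]], p@r_u / p@gamma_u - 1 / p@eta_u)
  expect_false(st0$degenerate)
  expect_true(steadyStates(p, criticalSignal(p))$degenerate)
  # strong-separation regime: both plateaus close to r/gamma
  corr_u <- (1 + p@eta_s * 0.05) / p@eta_u
  st <- steadyStates(p, 0.05)
  expect_lt(abs(st$u_pos[["u"]] - p@r_u / p@gamma_u), corr_u + 1e-12)
  expect_lt(abs(st$v_pos[["v"]] - p@r_v / p@gamma_v),
            (1 + p@eta_s * 0.05) /
              (p@eta_v * (1 + p@eta_s * p@eta_vs * 0.05)) + 1e-12)
  # a negative closed form is reported absent, not clamped
  plow <- modelParams(r_u = 0.1, r_v = 0.1, gamma_u = 1, gamma_v = 1,
                      eta_u = 5, eta_v = 403, eta_s = 5, eta_vs = 11)
  expect_null(steadyStates(plow, 0.5)$u_pos)
})

test_that("stability interval arithmetic and width identity hold", {
  p <- defaultParams()
  # equal rates, s_min = 0: lower bound equals -delta_eps_v exactly
  iv <- stabilityInterval(p, s_min = 0, s_max = 0.1)
  expect_equal(iv@delta_eps_min, log(p@eta_v))
  # width identity against direct evaluation for random parameters
  set.seed(31)
  for (i in 1:10) {
    pr <- modelParams(r_u = runif(1, 0.05, 1), r_v = runif(1, 0.05, 1),
                      gamma_u = runif(1, 0.5, 2), gamma_v = runif(1, 0.5, 2),
                      eta_u = runif(1, 10, 100), eta_v = runif(1, 10, 100),
                      eta_s = runif(1, 1, 10), eta_vs = runif(1, 1, 10))
    smax <- runif(1, 0.01, 1)
    ivr <- stabilityInterval(pr, s_min = 0, s_max = smax)
    expect_equal(ivr@delta_eps_max - ivr@delta_eps_min,
                 log(1 + pr@eta_s * pr@eta_vs * smax), tolerance = 1e-12)
  }
  expect_error(stabilityInterval(p, s_min = 0.2, s_max = 0.1), "s_min")
})

test_that("silent-state exclusion condition is strict", {
  base <- list(r_u = 0.1, gamma_u = 1, eta_u = 100, eta_s = 1, eta_vs = 2)
  p_true <- do.call(modelParams, c(base, list(r_v = 1, gamma_v = 1, eta_v = 2)))
  expect_true(exclusionCondition(p_true))
  p_edge <- do.call(modelParams, c(base, list(r_v = 1, gamma_v = 1, eta_v = 1)))
  expect_false(exclusionCondition(p_edge))   # boundary is not strict
  expect_true(exclusionCondition(defaultParams()))
  # when false (and u likewise subcritical), tiny expression decays to silence
  p_dec <- modelParams(r_u = 0.1, r_v = 0.1, gamma_u = 1, gamma_v = 1,
                       eta_u = 5, eta_v = 5, eta_s = 1, eta_vs = 2)
  expect_false(exclusionCondition(p_dec))
  fate <- single_cell_fate(p_dec, 0, u0 = 1e-6, v0 = 1e-6, t_end = 100)
  expect_lt(fate[["u"]], 1e-9)
  expect_lt(fate[["v"]], 1e-9)
})

test_that("neighbor tolerance bound lMax floors and clamps", {
  p <- defaultParams()
  expect_equal(lMax(setEtaU(p, log(p@eta_v) + 1e-6), 6), 0L)
  expect_equal(lMax(modelParams(r_u = 0.1, r_v = 0.1, gamma_u = 1,
                                gamma_v = 1, eta_u = 403.4288,
                                eta_v = 403.4288, eta_s = 5, eta_vs = 11),
                    6), 0L)
  # degree 6, gamma_v/r_v = 1, (eta_u-eta_v)/(eta_v eta_s eta_vs) = 0.4
  pc <- modelParams(r_u = 1, r_v = 1, gamma_u = 1, gamma_v = 1,
                    eta_u = 10 + 10 * 0.4 * 2, eta_v = 10,
                    eta_s = 2, eta_vs = 1)
  expect_equal(lMax(pc, 6), 2L)   # floor(2.4)
  # clamped at zero when eta_u < eta_v
  expect_equal(lMax(modelParams(r_u = 1, r_v = 1, gamma_u = 1, gamma_v = 1,
                                eta_u = 5, eta_v = 10, eta_s = 1,
                                eta_vs = 1), 6), 0L)
})
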