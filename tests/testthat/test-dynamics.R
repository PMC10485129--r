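# single-cell "tissue": one vertex, zero kernel, so s = 0 throughout
solo <- function() {
  g <- fatepattern:::.cellGraphFromAdjacency(matrix(FALSE, 1, 1))
  K <- suppressWarnings(neighborMeanKernel(g))
  list(g = g, K = K)
}

test_that("a single silent-signal cell converges to the u+ plateau", {
  p <- defaultParams()
  s <- solo()
  st <- simulateTissue(s$g, s$K, p, init = list(u = 1e-3, v = 1e-3))
  expect_true(st@converged)
  expect_equal(st@u, p@r_u / p@gamma_u - 1 / p@eta_u, tolerance = 1e-6)
  expect_lt(st@v, 1e-6)
})

test_that("the silent state is a fixed point and inputs are validated", {
  p <- defaultParams()
  fx <- small_fixture()
  K <- neighborMeanKernel(fx$graph)
  n <- nCells(fx$graph)
  st <- simulateTissue(fx$graph, K, p, init = list(u = rep(0, n),
                                                   v = rep(0, n)))
  expect_true(st@converged)
  expect_equal(st@steps, 0L)
  expect_true(all(st@u == 0) && all(st@v == 0))
  expect_error(simulateTissue(fx$graph, K, p,
                              init = list(u = rep(-1, n), v = rep(0, n))),
               "nonnegative")
  expect_error(simulateTissue(fx$graph, K, p, init = list(u = 0, v = 0)),
               "length")
  expect_error(simulateTissue(fx$graph, neighborMeanKernel(lineGraph(4)), p),
               "dimension")
})

test_that("compiled integrator agrees with the pure-R reference", {
  p <- defaultParams()
  fx <- small_fixture()
  K <- neighborMeanKernel(fx$graph)
  init <- randomInitialState(nCells(fx$graph), p, 5)
  steps <- 2000
  core <- fatepattern:::.eulerCore(kernelWeights(K), init$u, init$v,
                                   p@r_u, p@r_v, p@gamma_u, p@gamma_v,
                                   p@eta_u, p@eta_v, p@eta_s, p@eta_vs,
                                   0.01, 0, steps)
  ref <- fatepattern:::.eulerR(kernelWeights(K), init$u, init$v, p,
                               0.01, 0, steps)
  expect_equal(core$u, ref$u, tolerance = 1e-12)
  expect_equal(core$v, ref$v, tolerance = 1e-12)
})

test_that("simulation is deterministic and preserves nonnegativity", {
  p <- defaultParams()
  fx <- small_fixture()
  K <- neighborMeanKernel(fx$graph)
  st1 <- simulateTissue(fx$graph, K, p, seed = 3)
  st2 <- simulateTissue(fx$graph, K, p, seed = 3)
  expect_identical(st1@u, st2@u)
  expect_identical(st1@v, st2@v)
  expect_true(all(st1@u >= 0) && all(st1@v >= 0))
  expect_equal(st1@clipped, 0L)    # no undershoots at the default step
  expect_equal(st1@s, receivedSignal(K, st1@u), tolerance = 1e-12)
})

test_that("converged states satisfy the closed forms at the realized signal", {
  p <- defaultParams()
  fx <- small_fixture()
  K <- neighborMeanKernel(fx$graph)
  st <- classifyFates(simulateTissue(fx$graph, K, p, seed = 2))
  u_lab <- fateLabels(st) == "u+v-"
  u_pred <- p@r_u / p@gamma_u - (1 + p@eta_s * st@s) / p@eta_u
  v_pred <- p@r_v / p@gamma_v -
    (1 + p@eta_s * st@s) / (p@eta_v * (1 + p@eta_s * p@eta_vs * st@s))
  expect_lt(max(abs(st@u[u_lab] - u_pred[u_lab]) / u_pred[u_lab]), 1e-4)
  expect_lt(max(abs(st@v[!u_lab] - v_pred[!u_lab]) / v_pred[!u_lab]), 1e-4)
  expect_lt(max(st@v[u_lab]), 1e-6)
  expect_lt(max(st@u[!u_lab]), 1e-6)
})

test_that("halving the step barely moves the converged state", {
  p <- defaultParams()
  fx <- small_fixture()
  K <- neighborMeanKernel(fx$graph)
  init <- randomInitialState(nCells(fx$graph), p, 8)
  st1 <- simulateTissue(fx$graph, K, p, init = init, dt = 0.01)
  st2 <- simulateTissue(fx$graph, K, p, init = init, dt = 0.005)
  expect_true(st1@converged && st2@converged)
  scale <- pmax(st1@u + st1@v, 1e-6)
  expect_lt(max(abs(st1@u - st2@u) / scale), 1e-4)
  expect_lt(max(abs(st1@v - st2@v) / scale), 1e-4)
})

test_that("classification labels dominance and refuses bad input", {
  p <- defaultParams()
  mk <- function(u, v, conv = TRUE)
    new("TissueState", u = u, v = v, s = rep(0, length(u)),
        labels = rep(NA_character_, length(u)), time = 1,
        converged = conv, steps = 10L, clipped = 0L)
  st <- classifyFates(mk(c(0.09, 0, 0.05), c(0, 0.09, 0.05 + 1e-12)))
  expect_equal(fateLabels(st), c("u+v-", "u-v+", "undecided"))
  expect_error(classifyFates(mk(0.1, 0.1, conv = FALSE)), "non-converged")
  # labels of a real converged pattern are threshold-insensitive
  fx <- small_fixture()
  K <- neighborMeanKernel(fx$graph)
  sim <- simulateTissue(fx$graph, K, p, seed = 2)
  for (th in c(0.5, 1, 2)) {
    expect_identical(fateLabels(classifyFates(sim, ratio_threshold = th)),
                     fateLabels(classifyFates(sim)))
  }
})

test_that("patterns respect the neighbor tolerance bound lMax", {
  p <- defaultParams()   # mid-interval, strong separation regime
  fx <- small_fixture()
  K <- neighborMeanKernel(fx$graph)
  st <- classifyFates(simulateTissue(fx$graph, K, p, seed = 6))
  a <- adjacency(fx$graph)
  u_lab <- fateLabels(st) == "u+v-"
  same_nb <- vapply(which(u_lab), function(i) sum(u_lab[a[i, ]]), integer(1))
  expect_true(all(same_nb <= lMax(p, cellDegrees(fx$graph)[u_lab])))
})

test_that("homogeneous fates outside the interval, mixtures inside", {
  p <- defaultParams()
  fx <- small_fixture()
  K <- neighborMeanKernel(fx$graph)
  iv <- stabilityInterval(p)
  below <- classifyFates(simulateTissue(
    fx$graph, K, setEtaU(p, iv@delta_eps_min - 0.3), seed = 2))
  expect_true(all(fateLabels(below) == "u-v+"))
  above <- classifyFates(simulateTissue(
    fx$graph, K, setEtaU(p, iv@delta_eps_max + 0.3), seed = 2))
  expect_true(all(fateLabels(above) == "u+v-"))
  mid <- classifyFates(simulateTissue(fx$graph, K, p, seed = 2))
  expect_gt(sum(fateLabels(mid) == "u+v-"), 0)
  expect_gt(sum(fateLabels(mid) == "u-v+"), 0)
})

test_that("proportion sweep spans homogeneity to homogeneity monotonically", {
  p <- defaultParams()
  fx <- small_fixture()
  K <- neighborMeanKernel(fx$graph)
  sw <- proportionSweep(fx$graph, K, p, n_grid = 8, seed = 4)
  expect_true(all(sw@converged))
  expect_equal(sw@prop_u + sw@prop_v, rep(1, 8))
  expect_equal(sw@prop_u[1], 0)
  expect_equal(sw@prop_u[8], 1)
  expect_true(all(diff(sw@neg_delta_eps) - diff(sw@neg_delta_eps)[1] < 1e-9))
  expect_true(all(diff(sw@prop_u) >= -0.05))   # monotone up to jitter
})

test_that("bisection reaches an exact small-tissue split or flags", {
  p <- defaultParams()
  fx <- small_fixture()
  K <- neighborMeanKernel(fx$graph)
  n <- nCells(fx$graph)
  bi <- bisectRatio(fx$graph, K, p, c(n, 0), seed = 4, max_iter = 12)
  # all-u target pushes the search to the upper end of the interval
  expect_gt(bi$neg_delta_eps,
            stabilityInterval(p)@delta_eps_max - 0.1)
  expect_equal(unname(bi$counts["u"]), n)
  # bisection trace: count nondecreasing in -delta_eps_u up to jitter
  tr <- bi$trace[order(bi$trace$neg_delta_eps), ]
  expect_true(all(diff(tr$count_u) >= -2))
  expect_error(bisectRatio(fx$graph, K, p, c(3, 2), seed = 1), "sum")
})
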