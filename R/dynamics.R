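#' Seeded near-silent initial conditions
#'
#' The silent state (0, 0) is a fixed point, so pattern self-organization
#' needs strictly positive symmetric noise. Both factors start at
#' independent uniform draws in \code{[0.9, 1.1] * c0} with
#' \code{c0 = 1e-3 * r_u/gamma_u}, far below the steady-state plateau.
#'
#' @param n number of cells.
#' @param params a [ModelParams-class] object.
#' @param seed RNG seed.
#' @return list with vectors \code{u} and \code{v}.
#' @export
randomInitialState <- function(n, params, seed) {
  stopifnot(is(params, "ModelParams"), n >= 1)
  c0 <- 1e-3 * params@r_u / params@gamma_u
  .withSeed(.subSeed(seed, "init"), {
    list(u = stats::runif(n, 0.9, 1.1) * c0,
         v = stats::runif(n, 0.9, 1.1) * c0)
  })
}

#' Integrate the coupled tissue system to steady state
#'
#' Explicit (forward) Euler integration of the per-cell production/decay
#' dynamics, with the received signal recomputed from the current u levels
#' at every step (the signal is an instantaneous response, not a dynamic
#' species). Converged when the max-norm of the full derivative vector
#' falls below \code{tol}. Negative undershoots are clipped at 0 and
#' counted (a warning summarizes them; none occur at the default step).
#'
#' @param graph a [CellGraph-class] object (used for dimension checks).
#' @param kernel a [SignalKernel-class] object matching the graph.
#' @param params a [ModelParams-class] object.
#' @param init list with vectors \code{u}, \code{v}; default
#'   [randomInitialState()] from \code{seed}.
#' @param dt Euler step; default \code{1e-2 * min(1/gamma_u, 1/gamma_v)}.
#' @param tol convergence threshold on \code{max(|du/dt|, |dv/dt|)}.
#' @param max_steps step cap; hitting it returns \code{converged = FALSE}.
#' @param seed seed for the default initial conditions.
#' @return a [TissueState-class] object (labels unset; see
#'   [classifyFates()]).
#' @export
simulateTissue <- function(graph, kernel, params, init = NULL, dt = NULL,
                           tol = 1e-8, max_steps = 1e7, seed = 1) {
  stopifnot(is(graph, "CellGraph"), is(kernel, "SignalKernel"),
            is(params, "ModelParams"))
  n <- nCells(graph)
  if (nrow(kernel@weights) != n)
    stop("kernel dimension does not match graph", call. = FALSE)
  if (is.null(init)) init <- randomInitialState(n, params, seed)
  u <- as.numeric(init$u); v <- as.numeric(init$v)
  if (length(u) != n || length(v) != n)
    stop("init vectors must have length nCells(graph)", call. = FALSE)
  if (any(u < 0) || any(v < 0))
    stop("initial concentrations must be nonnegative", call. = FALSE)
  if (is.null(dt)) dt <- 1e-2 * min(1 / params@gamma_u, 1 / params@gamma_v)
  stopifnot(dt > 0)

  res <- .eulerCore(kernel@weights, u, v,
                    params@r_u, params@r_v, params@gamma_u, params@gamma_v,
                    params@eta_u, params@eta_v, params@eta_s, params@eta_vs,
                    dt, tol, max_steps)
  if (res$clipped > 0)
    warning(sprintf("%d negative undershoots clipped to 0", res$clipped))
  new("TissueState", u = res$u, v = res$v, s = res$s,
      labels = rep(NA_character_, n), time = res$steps * dt,
      converged = res$converged, steps = as.integer(res$steps),
      clipped = as.integer(res$clipped))
}

# Pure-R reference integrator, identical update rule to the compiled core;
# used as the independent cross-check in the test suite.
.eulerR <- function(A, u, v, params, dt, tol, max_steps) {
  ru <- params@r_u; rv <- params@r_v
  gu <- params@gamma_u; gv <- params@gamma_v
  eu <- params@eta_u; ev <- params@eta_v; es <- params@eta_s
  evs <- params@eta_vs
  clipped <- 0L
  converged <- FALSE
  step <- 0L
  while (step < max_steps) {
    s <- as.numeric(A %*% u)
    act <- 1 + es * evs * s
    den <- 1 + ev * v * act + eu * u + es * s
    du <- ru * (eu * u) / den - gu * u
    dv <- rv * (ev * v * act) / den - gv * v
    if (max(abs(c(du, dv))) < tol) { converged <- TRUE; break }
    u <- pmax(u + dt * du, 0)
    v <- pmax(v + dt * dv, 0)
    u[u < 1e-30] <- 0          # flush dynamically dead values, as in the core
    v[v < 1e-30] <- 0
    step <- step + 1L
  }
  list(u = u, v = v, s = as.numeric(A %*% u), steps = step,
       converged = converged)
}

#' Classify converged cells into the two fates
#'
#' Cell i is labeled "u+v-" iff \code{u_i > ratio_threshold * v_i} (simple
#' dominance at the default threshold 1), "u-v+" otherwise; near-ties
#' within relative tolerance \code{tie_tol} become "undecided". Because
#' steady states are near one-hot, labels are insensitive to the threshold
#' over a wide range.
#'
#' @param state a converged [TissueState-class] object.
#' @param ratio_threshold dominance ratio (default 1).
#' @param tie_tol relative tolerance for calling a tie.
#' @return the state with the \code{labels} slot filled (see
#'   [fateLabels()]).
#' @export
classifyFates <- function(state, ratio_threshold = 1, tie_tol = 1e-6) {
  stopifnot(is(state, "TissueState"))
  if (!state@converged)
    stop("refusing to classify a non-converged state", call. = FALSE)
  lhs <- state@u
  rhs <- ratio_threshold * state@v
  scale <- pmax(lhs, rhs, .Machine$double.xmin)
  tie <- abs(lhs - rhs) <= tie_tol * scale
  state@labels <- ifelse(tie, "undecided", ifelse(lhs > rhs, "u+v-", "u-v+"))
  state
}
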