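#' Nearest-neighbor-mean signal kernel
#'
#' The received signal of cell i is the mean u level of its direct
#' neighbors: \eqn{s_i = |N_G(i)|^{-1} \sum_{j \in N_G(i)} u_j}, i.e.
#' \code{s = A u} with \code{A_ij = 1/|N_G(i)|} for neighbors, else 0.
#' Isolated cells get an all-zero row (they receive s = 0) with a warning.
#'
#' @param graph a [CellGraph-class] object.
#' @return a [SignalKernel-class] object of kind "neighbor-mean".
#' @export
neighborMeanKernel <- function(graph) {
  stopifnot(is(graph, "CellGraph"))
  deg <- graph@degrees
  if (any(deg == 0))
    warning("isolated cell(s) receive signal 0: ",
            paste(which(deg == 0), collapse = ", "))
  w <- graph@adjacency / pmax(deg, 1L)
  new("SignalKernel", weights = w, kind = "neighbor-mean",
      q = NA_real_, a = NA_real_)
}

#' Distance-based dispersion signal kernel
#'
#' Each cell's emission (its u level) reaches cell i weighted by
#' \code{q^(d_ij - 1)}: direct neighbors receive the full weight, and each
#' further hop multiplies the contribution by the dispersion q. Weights are
#' normalized by the largest total weight over receiving cells,
#' \deqn{A_{ij} = a\, q^{d_{ij}-1}, \quad
#'   a = \left(\max_k \sum_{l \ne k} q^{d_{kl}-1}\right)^{-1},}
#' so the best-connected cell has row sum 1. The convention 0^0 = 1 makes
#' q = 0 the pure contact-indicator kernel; q = 1 weights every other cell
#' equally (a = 1/(N-1)) and therefore requires a connected graph. For
#' q < 1 unreachable pairs (d = Inf) get weight 0.
#'
#' @param graph a [CellGraph-class] object.
#' @param q dispersion parameter in [0, 1].
#' @return a [SignalKernel-class] object of kind "dispersion".
#' @examples
#' g <- lineGraph(6)
#' k <- dispersionKernel(g, 0.5)
#' kernelWeights(k)[1, ] / kernelWeights(k)[1, 2]   # 1, 0.5, 0.25, ...
#' @export
dispersionKernel <- function(graph, q) {
  stopifnot(is(graph, "CellGraph"))
  if (!is.finite(q) || q < 0 || q > 1)
    stop("q must lie in [0, 1]", call. = FALSE)
  d <- graph@distances
  if (q == 1 && any(is.infinite(d)))
    stop("q = 1 is ill-posed on a disconnected graph", call. = FALSE)
  n <- nrow(d)
  w <- matrix(0, n, n)
  off <- row(d) != col(d)
  if (q == 0) {
    w[off] <- as.numeric(d[off] == 1)          # 0^0 = 1 convention
  } else {
    w[off] <- q^(d[off] - 1)
    w[off][is.infinite(d[off])] <- 0
  }
  a <- 1 / max(rowSums(w))
  new("SignalKernel", weights = a * w, kind = "dispersion", q = q, a = a)
}

#' Apply a kernel: received signal from u levels
#'
#' @param kernel a [SignalKernel-class] object.
#' @param u per-cell u levels.
#' @return numeric vector s = A u.
#' @export
receivedSignal <- function(kernel, u) {
  stopifnot(is(kernel, "SignalKernel"))
  if (length(u) != nrow(kernel@weights))
    stop("u length must match kernel dimension", call. = FALSE)
  as.numeric(kernel@weights %*% u)
}

#' Analytic bounds of the received signal
#'
#' In a heterogeneous steady state some cells are silent in u, so the
#' minimum signal is 0; the u plateau is bounded by \code{r_u/gamma_u}, and
#' both kernel kinds have maximum row sum 1, so the maximum signal
#' approaches \code{r_u/gamma_u}. The approximation is accurate when the
#' plateau correction \code{(1 + eta_s * r_u/gamma_u)/eta_u} is small
#' against \code{r_u/gamma_u} (checked; warns when the separation is less
#' than a factor of 10).
#'
#' @param params a [ModelParams-class] object.
#' @param warn warn when the separation condition fails.
#' @return named numeric c(s_min = 0, s_max = r_u/gamma_u).
#' @export
signalBounds <- function(params, warn = TRUE) {
  stopifnot(is(params, "ModelParams"))
  smax <- params@r_u / params@gamma_u
  corr <- (1 + params@eta_s * smax) / params@eta_u
  if (warn && corr > 0.1 * smax)
    warning(sprintf(paste0("steady-state correction %.3g is not small against ",
                           "r_u/gamma_u = %.3g; the signal ceiling and the ",
                           "stability-interval approximation are inaccurate"),
                    corr, smax))
  c(s_min = 0, s_max = smax)
}
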