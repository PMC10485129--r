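#' Analytic Jacobian of the coupled tissue ODE system
#'
#' Assembles the 2N x 2N linearization of the tissue dynamics at a given
#' state. With s = A u (A the signal kernel acting on the u levels), the
#' chain rule couples cells through the kernel:
#' \deqn{L = \begin{pmatrix} r_u A_{uu} - \gamma_u I & r_u A_{uv} \\
#'   r_v A_{vu} & r_v A_{vv} - \gamma_v I \end{pmatrix}}
#' where \eqn{A_{uu} = \partial p_u/\partial u + (\partial p_u/\partial s) A},
#' \eqn{A_{vu} = \partial p_v/\partial u + (\partial p_v/\partial s) A}, and
#' \eqn{A_{uv}, A_{vv}} are the diagonal v-derivatives (s does not depend on
#' v). Requires the specialized model
#' (\code{eta_uv = eta_us = eta_uvs = 0}).
#'
#' @param u,v per-cell state vectors (length N, matching the kernel).
#' @param kernel a [SignalKernel-class] object.
#' @param params a [ModelParams-class] object.
#' @return list with the 2N x 2N \code{matrix}, all complex
#'   \code{eigenvalues}, and \code{leading} (the eigenvalue with largest real
#'   part).
#' @export
grnJacobian <- function(u, v, kernel, params) {
  stopifnot(is(kernel, "SignalKernel"), is(params, "ModelParams"))
  if (params@eta_uv != 0 || params@eta_us != 0 || params@eta_uvs != 0)
    stop("analytic Jacobian is implemented for the specialized model only",
         call. = FALSE)
  A <- kernel@weights
  n <- nrow(A)
  if (length(u) != n || length(v) != n)
    stop("state length must match kernel dimension", call. = FALSE)
  s <- as.numeric(A %*% u)
  eu <- params@eta_u; ev <- params@eta_v; es <- params@eta_s
  evs <- params@eta_vs
  act <- 1 + es * evs * s                       # cooperative activation factor
  den <- 1 + ev * v * act + eu * u + es * s
  den2 <- den^2
  dpu_du <- eu * (1 + ev * v * act + es * s) / den2
  dpu_dv <- -eu * u * ev * act / den2
  dpv_du <- -ev * v * act * eu / den2
  dpv_dv <- ev * act * (1 + eu * u + es * s) / den2
  dpu_ds <- -eu * es * u * (1 + ev * evs * v) / den2
  dpv_ds <- ev * es * v * (evs + eu * evs * u - 1) / den2

  Auu <- diag(dpu_du, n) + dpu_ds * A           # row-scaled kernel coupling
  Avu <- diag(dpv_du, n) + dpv_ds * A
  L <- rbind(
    cbind(params@r_u * Auu - diag(params@gamma_u, n),
          diag(params@r_u * dpu_dv, n)),
    cbind(params@r_v * Avu,
          diag(params@r_v * dpv_dv, n) - diag(params@gamma_v, n)))
  ev_all <- eigen(L, only.values = TRUE)$values
  list(matrix = L, eigenvalues = ev_all,
       leading = ev_all[which.max(Re(ev_all))])
}

#' Homogeneous tissue state at a fate plateau
#'
#' Builds the self-consistent all-u+v- or all-u-v+ state on a tissue: for
#' the u+ fate the per-cell u levels solve the linear fixed point
#' \code{u = r_u/gamma_u - (1 + eta_s A u)/eta_u}; for the v+ fate u = 0
#' everywhere (so s = 0) and v sits at its closed-form plateau.
#' Used to probe the stability interval endpoints.
#'
#' @param kernel a [SignalKernel-class] object.
#' @param params a [ModelParams-class] object.
#' @param fate "u+v-" or "u-v+".
#' @return list with vectors \code{u}, \code{v}, \code{s}.
#' @export
homogeneousState <- function(kernel, params, fate = c("u+v-", "u-v+")) {
  fate <- match.arg(fate)
  A <- kernel@weights
  n <- nrow(A)
  if (fate == "u-v+") {
    v <- rep(params@r_v / params@gamma_v - 1 / params@eta_v, n)
    if (any(v < 0)) stop("v+ plateau is negative for these parameters", call. = FALSE)
    return(list(u = rep(0, n), v = v, s = rep(0, n)))
  }
  # solve (I + (eta_s/eta_u) A) u = (r_u/gamma_u - 1/eta_u) 1
  M <- diag(n) + (params@eta_s / params@eta_u) * A
  u <- solve(M, rep(params@r_u / params@gamma_u - 1 / params@eta_u, n))
  if (any(u < 0)) stop("u+ plateau is negative for these parameters", call. = FALSE)
  list(u = u, v = rep(0, n), s = as.numeric(A %*% u))
}
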