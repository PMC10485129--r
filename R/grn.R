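#' Promoter binding probabilities of the two factors
#'
#' Boltzmann-statistics occupancy of the two promoters given the
#' concentrations of u, v and the received signal s. The general form sums
#' seven weighted binding configurations (u, v, s alone; the pairs uv, us,
#' vs; the triple uvs) in a common partition sum; the specialized model
#' (\code{eta_uv = eta_us = eta_uvs = 0}) is the blocking-inhibition case
#' \deqn{p_u = \frac{\eta_u u}{1 + \eta_v v (1 + \eta_s \eta_{vs} s) +
#'   \eta_u u + \eta_s s}}
#' with \eqn{p_v} obtained by exchanging the roles of u and v (the signal
#' then cooperates with v through \eqn{\eta_{vs}}).
#'
#' @param u,v,s nonnegative concentrations / signal (vectors recycle to a
#'   common length).
#' @param params a [ModelParams-class] object.
#' @return list with numeric vectors \code{p_u} and \code{p_v}, each in
#'   \code{[0, 1]} with \code{p_u + p_v <= 1}.
#' @examples
#' p <- defaultParams()
#' bindingProbabilities(0.05, 0, 0, p)
#' @export
bindingProbabilities <- function(u, v, s, params) {
  stopifnot(is(params, "ModelParams"))
  n <- max(length(u), length(v), length(s))
  u <- rep_len(as.numeric(u), n); v <- rep_len(as.numeric(v), n)
  s <- rep_len(as.numeric(s), n)
  if (any(u < 0) || any(v < 0) || any(s < 0))
    stop("concentrations and signals must be nonnegative", call. = FALSE)
  with(paramsAsList(params), {
    den <- 1 + eta_u * u + eta_v * v + eta_s * s +
      eta_u * eta_v * eta_uv * u * v +
      eta_u * eta_s * eta_us * u * s +
      eta_v * eta_s * eta_vs * v * s +
      eta_u * eta_v * eta_s * eta_uvs * u * v * s
    num_u <- eta_u * u + eta_u * eta_v * eta_uv * u * v +
      eta_u * eta_s * eta_us * u * s +
      eta_u * eta_v * eta_s * eta_uvs * u * v * s
    num_v <- eta_v * v + eta_u * eta_v * eta_uv * u * v +
      eta_v * eta_s * eta_vs * v * s +
      eta_u * eta_v * eta_s * eta_uvs * u * v * s
    list(p_u = num_u / den, p_v = num_v / den)
  })
}

#' Right-hand side of the tissue ODE system
#'
#' Per-cell production/decay dynamics
#' \deqn{du_i/dt = r_u p_u(u_i, v_i, s_i) - \gamma_u u_i} and analogously for
#' v. Cells are coupled only through the received signal vector s.
#'
#' @param u,v per-cell concentration vectors (equal length, nonnegative).
#' @param s per-cell received signal (same length).
#' @param params a [ModelParams-class] object.
#' @return list with derivative vectors \code{du} and \code{dv}.
#' @export
grnRHS <- function(u, v, s, params) {
  if (length(u) != length(v) || length(u) != length(s))
    stop("u, v and s must have the same length", call. = FALSE)
  p <- bindingProbabilities(u, v, s, params)
  list(du = params@r_u * p$p_u - params@gamma_u * u,
       dv = params@r_v * p$p_v - params@gamma_v * v)
}

#' Critical signal value at which a cell's fate switches
#'
#' Below this received-signal value a single cell converges to the u+v-
#' state, above it to u-v+; exactly at it the two nonzero steady-state
#' branches merge into a degenerate line.
#' \deqn{s^* = \frac{r_u \gamma_v \eta_u - r_v \gamma_u \eta_v}
#'                  {r_v \gamma_u \eta_v \eta_s \eta_{vs}}}
#' A negative value means every nonnegative signal selects u-v+.
#'
#' @param params a [ModelParams-class] object.
#' @return the critical signal (may be negative).
#' @export
criticalSignal <- function(params) {
  stopifnot(is(params, "ModelParams"))
  den <- params@r_v * params@gamma_u * params@eta_v * params@eta_s * params@eta_vs
  if (den == 0) stop("eta_s * eta_vs must be positive", call. = FALSE)
  (params@r_u * params@gamma_v * params@eta_u -
     params@r_v * params@gamma_u * params@eta_v) / den
}

#' Closed-form steady states of a single cell at fixed signal
#'
#' Returns the trivial state (0, 0) and, where they exist as nonnegative
#' concentrations, the two fate states
#' \deqn{u^+v^-: \quad u = r_u/\gamma_u - (1 + \eta_s s)/\eta_u, \; v = 0}
#' \deqn{u^-v^+: \quad u = 0, \; v = r_v/\gamma_v -
#'   (1 + \eta_s s)/(\eta_v (1 + \eta_s \eta_{vs} s))}
#' A branch whose closed form is negative is reported as absent (NULL), not
#' clamped. When s sits on the critical signal (within \code{rel_tol}
#' relative tolerance) the two branches merge into a line of steady states
#' and the \code{degenerate} flag is set.
#'
#' @param params a [ModelParams-class] object.
#' @param s received signal (single nonnegative value).
#' @param rel_tol relative tolerance for flagging the degenerate case.
#' @return list with elements \code{null_state}, \code{u_pos}, \code{v_pos}
#'   (named numeric c(u, v) or NULL) and logical \code{degenerate}.
#' @export
steadyStates <- function(params, s, rel_tol = 1e-9) {
  stopifnot(is(params, "ModelParams"), length(s) == 1L, s >= 0)
  u_plus <- params@r_u / params@gamma_u - (1 + params@eta_s * s) / params@eta_u
  v_plus <- params@r_v / params@gamma_v -
    (1 + params@eta_s * s) / (params@eta_v * (1 + params@eta_s * params@eta_vs * s))
  s_star <- criticalSignal(params)
  degenerate <- abs(s - s_star) / max(abs(s_star), 1e-12) < rel_tol
  list(null_state = c(u = 0, v = 0),
       u_pos = if (u_plus >= 0) c(u = u_plus, v = 0) else NULL,
       v_pos = if (v_plus >= 0) c(u = 0, v = v_plus) else NULL,
       degenerate = degenerate)
}

#' Stability interval for heterogeneous patterns
#'
#' The range of \code{-delta_eps_u} over which both homogeneous tissue
#' states are linearly unstable, so the tissue must settle into a mixture of
#' the two fates:
#' \deqn{\Delta\varepsilon_{min/max} = -\Delta\varepsilon_v +
#'   \log(1 + \eta_s \eta_{vs}\, s_{min/max}) +
#'   \log\!\left(\frac{r_v \gamma_u}{r_u \gamma_v}\right)}
#' By default the extreme signals are taken from [signalBounds()]
#' (\code{s_min = 0}, \code{s_max = r_u/gamma_u}), which is the
#' approximation valid whenever the correction
#' \code{(1 + eta_s s_max)/eta_u} is small against \code{r_u/gamma_u}.
#'
#' @param params a [ModelParams-class] object.
#' @param s_min,s_max extreme received-signal values (0 <= s_min <= s_max);
#'   defaults are the analytic signal bounds.
#' @return a [StabilityInterval-class] object.
#' @examples
#' stabilityInterval(defaultParams())  # (6, 7.87) with the shipped defaults
#' @export
stabilityInterval <- function(params, s_min = NULL, s_max = NULL) {
  stopifnot(is(params, "ModelParams"))
  if (is.null(s_min) || is.null(s_max)) {
    b <- signalBounds(params)
    if (is.null(s_min)) s_min <- b[["s_min"]]
    if (is.null(s_max)) s_max <- b[["s_max"]]
  }
  if (s_min < 0 || s_min > s_max)
    stop("need 0 <= s_min <= s_max", call. = FALSE)
  base <- log(params@eta_v) + log(params@r_v * params@gamma_u /
                                    (params@r_u * params@gamma_v))
  new("StabilityInterval",
      delta_eps_min = base + log1p(params@eta_s * params@eta_vs * s_min),
      delta_eps_max = base + log1p(params@eta_s * params@eta_vs * s_max),
      s_min = s_min, s_max = s_max)
}

#' Does the parameter set exclude the silent (0, 0) state?
#'
#' The no-expression state is linearly unstable (hence excluded as a cell
#' fate) iff \code{eta_v > gamma_v / r_v}, strictly.
#'
#' @param params a [ModelParams-class] object.
#' @return TRUE iff the silent state is unstable.
#' @export
exclusionCondition <- function(params) {
  stopifnot(is(params, "ModelParams"))
  params@eta_v > params@gamma_v / params@r_v
}

#' Maximum number of same-fate neighbors a u+v- cell tolerates
#'
#' Under nearest-neighbor-mean signaling with neighbors at the steady-state
#' plateau, a cell keeps the u+v- fate only while the number of u+v-
#' neighbors l satisfies
#' \deqn{l \le l^{max} = \left\lfloor |N_G(i)|\, \frac{\gamma_v}{r_v}\,
#'   \frac{\eta_u - \eta_v}{\eta_v \eta_s \eta_{vs}} \right\rfloor}
#' clamped below at 0 when \code{eta_u < eta_v}.
#'
#' @param params a [ModelParams-class] object.
#' @param degree neighbor count(s) |N_G(i)| (>= 1).
#' @return nonnegative integer vector.
#' @export
lMax <- function(params, degree) {
  stopifnot(is(params, "ModelParams"), all(degree >= 1))
  val <- degree * (params@gamma_v / params@r_v) *
    (params@eta_u - params@eta_v) /
    (params@eta_v * params@eta_s * params@eta_vs)
  as.integer(pmax(0, floor(val)))
}
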