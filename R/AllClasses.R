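#' @import methods
NULL

#' Model parameters of the two-factor switch
#'
#' Holds every rate and energy coefficient of the gene regulatory network:
#' two antagonistic, auto-activating transcription factors u and v, with an
#' extracellular signal s that inhibits u and cooperatively activates v.
#' Energy coefficients eta are Boltzmann weights, interchangeable with energy
#' differences via \code{eta = exp(-delta_eps)}.
#'
#' @slot r_u,r_v production rates (concentration/time, > 0).
#' @slot gamma_u,gamma_v decay rates (1/time, > 0).
#' @slot eta_u,eta_v,eta_s energy coefficients (dimensionless, > 0).
#' @slot eta_vs cooperative signal-v activation coefficient (>= 1).
#' @slot eta_uv,eta_us,eta_uvs general interaction coefficients (>= 0);
#'   all zero in the specialized blocking-inhibition model.
#'
#' @seealso [modelParams()], [defaultParams()]
#' @export
setClass("ModelParams",
  slots = c(
    r_u = "numeric", r_v = "numeric",
    gamma_u = "numeric", gamma_v = "numeric",
    eta_u = "numeric", eta_v = "numeric", eta_s = "numeric",
    eta_vs = "numeric",
    eta_uv = "numeric", eta_us = "numeric", eta_uvs = "numeric"
  )
)

setValidity("ModelParams", function(object) {
  msgs <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  for (nm in slotNames(object)) {
    if (!one(slot(object, nm))) msgs <- c(msgs, sprintf("'%s' must be a single finite number", nm))
  }
  if (length(msgs)) return(msgs)
  for (nm in c("r_u", "r_v", "gamma_u", "gamma_v", "eta_u", "eta_v", "eta_s")) {
    if (slot(object, nm) <= 0) msgs <- c(msgs, sprintf("'%s' must be strictly positive", nm))
  }
  if (object@eta_vs < 1) msgs <- c(msgs, "'eta_vs' must be >= 1 (signal activates v cooperatively)")
  for (nm in c("eta_uv", "eta_us", "eta_uvs")) {
    if (slot(object, nm) < 0) msgs <- c(msgs, sprintf("'%s' must be >= 0", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' Stability interval for the energy difference -delta_eps_u
#'
#' The open interval of \code{-delta_eps_u} values for which both homogeneous
#' tissue states (all u+v- or all u-v+) are linearly unstable, so that only
#' heterogeneous two-type patterns are stable. Bounds are
#' \code{-delta_eps_v + log(1 + eta_s*eta_vs*s) + log(r_v*gamma_u/(r_u*gamma_v))}
#' evaluated at the extreme signals \code{s_min} and \code{s_max}.
#'
#' @slot delta_eps_min,delta_eps_max lower/upper bound on -delta_eps_u.
#' @slot s_min,s_max the extreme signal values used.
#' @export
setClass("StabilityInterval",
  slots = c(delta_eps_min = "numeric", delta_eps_max = "numeric",
            s_min = "numeric", s_max = "numeric")
)

setValidity("StabilityInterval", function(object) {
  if (object@s_min > object@s_max) return("s_min must be <= s_max")
  if (object@s_max > object@s_min && object@delta_eps_min >= object@delta_eps_max)
    return("delta_eps_min must be < delta_eps_max when s_max > s_min")
  TRUE
})

#' A two-dimensional tissue of equal-radius cells
#'
#' @slot positions numeric N x 2 matrix of cell centroids (length units).
#' @slot radius common cell radius (length units).
#' @export
setClass("Tissue", slots = c(positions = "matrix", radius = "numeric"))

setValidity("Tissue", function(object) {
  p <- object@positions
  if (!is.numeric(p) || ncol(p) != 2L) return("positions must be a numeric N x 2 matrix")
  if (nrow(p) < 2L) return("a tissue needs at least 2 cells")
  if (!all(is.finite(p))) return("positions must be finite")
  if (length(object@radius) != 1L || !is.finite(object@radius) || object@radius <= 0)
    return("radius must be a single positive number")
  if (anyDuplicated(p)) return("no two cell positions may coincide")
  TRUE
})

#' Cell contact graph with hop distances
#'
#' Adjacency is the symmetric contact relation (touching cells); distances
#' d_ij are unweighted shortest-path lengths in hops, with Inf marking
#' unreachable pairs.
#'
#' @slot adjacency logical symmetric N x N matrix, zero diagonal.
#' @slot distances numeric N x N matrix of hop counts (Inf if unreachable).
#' @slot degrees integer per-cell neighbor counts.
#' @export
setClass("CellGraph",
  slots = c(adjacency = "matrix", distances = "matrix", degrees = "integer")
)

setValidity("CellGraph", function(object) {
  a <- object@adjacency; d <- object@distances
  n <- nrow(a)
  if (ncol(a) != n || nrow(d) != n || ncol(d) != n) return("adjacency/distances must be square, same size")
  if (!is.logical(a)) return("adjacency must be logical")
  if (any(diag(a))) return("adjacency diagonal must be FALSE")
  if (!identical(a, t(a))) return("adjacency must be symmetric")
  if (any(diag(d) != 0)) return("self distances must be 0")
  if (!isTRUE(all.equal(d[a], rep(1, sum(a))))) return("d_ij must be 1 exactly on adjacency support")
  if (any(d[!a & row(a) != col(a)] <= 1)) return("non-adjacent distinct pairs must have d > 1")
  if (!identical(object@degrees, as.integer(rowSums(a)))) return("degrees must equal adjacency row sums")
  TRUE
})

#' Signal kernel: the N x N weight matrix mapping u levels to received signal
#'
#' Kind "neighbor-mean" averages over direct neighbors (rows sum to 1 for
#' non-isolated cells). Kind "dispersion" weights cell j's emission by
#' \code{a * q^(d_ij - 1)}, with the normalization a chosen so the maximum
#' row sum equals 1.
#'
#' @slot weights nonnegative N x N matrix with zero diagonal.
#' @slot kind "neighbor-mean" or "dispersion".
#' @slot q dispersion parameter in [0, 1] (NA for neighbor-mean).
#' @slot a normalization scalar (NA for neighbor-mean).
#' @export
setClass("SignalKernel",
  slots = c(weights = "matrix", kind = "character", q = "numeric", a = "numeric")
)

setValidity("SignalKernel", function(object) {
  w <- object@weights
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (any(w < 0)) return("weights must be nonnegative")
  if (any(diag(w) != 0)) return("weights diagonal must be zero")
  if (!object@kind %in% c("neighbor-mean", "dispersion")) return("unknown kernel kind")
  if (object@kind == "dispersion") {
    if (!is.finite(object@q) || object@q < 0 || object@q > 1) return("q must lie in [0, 1]")
    rs <- rowSums(w)
    if (abs(max(rs) - 1) > 1e-8) return("dispersion kernel max row sum must equal 1")
  }
  TRUE
})

#' Per-cell state of a tissue simulation
#'
#' @slot u,v per-cell concentrations (nonnegative).
#' @slot s per-cell received signal (kernel applied to u).
#' @slot labels per-cell fate: "u+v-", "u-v+" or "undecided"
#'   (NA before classification).
#' @slot time elapsed model time.
#' @slot converged TRUE if the max-norm of the derivative fell below tolerance.
#' @slot steps integration steps taken.
#' @slot clipped number of negative undershoots clipped to 0.
#' @export
setClass("TissueState",
  slots = c(u = "numeric", v = "numeric", s = "numeric", labels = "character",
            time = "numeric", converged = "logical", steps = "integer",
            clipped = "integer")
)

setValidity("TissueState", function(object) {
  n <- length(object@u)
  if (length(object@v) != n || length(object@s) != n || length(object@labels) != n)
    return("u, v, s, labels must have equal length")
  if (any(object@u < 0) || any(object@v < 0)) return("concentrations must be nonnegative")
  ok <- object@labels %in% c("u+v-", "u-v+", "undecided") | is.na(object@labels)
  if (!all(ok)) return("labels must be 'u+v-', 'u-v+', 'undecided' or NA")
  TRUE
})

#' Result of a proportion sweep over the stability interval
#'
#' @slot neg_delta_eps equidistant grid of -delta_eps_u values.
#' @slot prop_u,prop_v fate proportions at each grid value.
#' @slot count_u,count_v fate counts at each grid value.
#' @slot converged per-value convergence flag.
#' @slot seed seed used for the initial conditions.
#' @export
setClass("SweepResult",
  slots = c(neg_delta_eps = "numeric", prop_u = "numeric", prop_v = "numeric",
            count_u = "integer", count_v = "integer",
            converged = "logical", seed = "integer")
)

setValidity("SweepResult", function(object) {
  m <- length(object@neg_delta_eps)
  if (any(lengths(list(object@prop_u, object@prop_v, object@converged)) != m))
    return("grid and per-value vectors must have equal length")
  if (m >= 2) {
    step <- diff(object@neg_delta_eps)
    if (max(abs(step - step[1])) > 1e-9 * max(abs(step)))
      return("grid must be equidistant")
  }
  if (any(abs(object@prop_u + object@prop_v - 1) > 1e-12))
    return("proportions must sum to 1 at each grid point")
  TRUE
})

#' Graph-distance pair correlation function result
#'
#' Ordered-pair counts per hop distance k and their normalization by the
#' random-labeling pairing probabilities.
#'
#' @slot k hop distances with at least one pair.
#' @slot pairs,pairs_u,pairs_v |S_k|, |S^u_k|, |S^v_k| ordered-pair counts.
#' @slot rho_u,rho_v normalized correlations (NA if only counts were computed).
#' @slot n_u,n_v,n total u+v- cells, u-v+ cells, and all cells.
#' @export
setClass("PCFResult",
  slots = c(k = "integer", pairs = "numeric", pairs_u = "numeric",
            pairs_v = "numeric", rho_u = "numeric", rho_v = "numeric",
            n_u = "integer", n_v = "integer", n = "integer")
)

setValidity("PCFResult", function(object) {
  m <- length(object@k)
  if (any(lengths(list(object@pairs, object@pairs_u, object@pairs_v,
                       object@rho_u, object@rho_v)) != m))
    return("per-distance vectors must have equal length")
  if (any(object@pairs_u + object@pairs_v > object@pairs))
    return("|S^u_k| + |S^v_k| must not exceed |S_k|")
  if (any(object@rho_u < 0, na.rm = TRUE) || any(object@rho_v < 0, na.rm = TRUE))
    return("correlations must be nonnegative")
  TRUE
})
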