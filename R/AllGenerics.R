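#' @name fatepattern-accessors
#' @title Accessors for fatepattern classes
#' @description Small accessor generics so user code never touches slots.
#' @param x an object of the documented class
#' @return the requested component
NULL

#' @rdname fatepattern-accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname fatepattern-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname fatepattern-accessors
#' @export
setGeneric("cellRadius", function(x) standardGeneric("cellRadius"))

#' @rdname fatepattern-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname fatepattern-accessors
#' @export
setGeneric("graphDistances", function(x) standardGeneric("graphDistances"))

#' @rdname fatepattern-accessors
#' @export
setGeneric("cellDegrees", function(x) standardGeneric("cellDegrees"))

#' @rdname fatepattern-accessors
#' @export
setGeneric("kernelWeights", function(x) standardGeneric("kernelWeights"))

#' @rdname fatepattern-accessors
#' @export
setGeneric("fateLabels", function(x) standardGeneric("fateLabels"))

setMethod("nCells", "Tissue", function(x) nrow(x@positions))
setMethod("nCells", "CellGraph", function(x) nrow(x@adjacency))
setMethod("nCells", "TissueState", function(x) length(x@u))
setMethod("positions", "Tissue", function(x) x@positions)
setMethod("cellRadius", "Tissue", function(x) x@radius)
setMethod("adjacency", "CellGraph", function(x) x@adjacency)
setMethod("graphDistances", "CellGraph", function(x) x@distances)
setMethod("cellDegrees", "CellGraph", function(x) x@degrees)
setMethod("kernelWeights", "SignalKernel", function(x) x@weights)
setMethod("fateLabels", "TissueState", function(x) x@labels)

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams\n")
  cat(sprintf("  r_u=%g gamma_u=%g  r_v=%g gamma_v=%g\n",
              object@r_u, object@gamma_u, object@r_v, object@gamma_v))
  cat(sprintf("  eta_u=%g (-delta_eps_u=%.4g)  eta_v=%g (-delta_eps_v=%.4g)\n",
              object@eta_u, log(object@eta_u), object@eta_v, log(object@eta_v)))
  cat(sprintf("  eta_s=%g  eta_vs=%g  (eta_uv=%g eta_us=%g eta_uvs=%g)\n",
              object@eta_s, object@eta_vs, object@eta_uv, object@eta_us, object@eta_uvs))
})

setMethod("show", "StabilityInterval", function(object) {
  cat(sprintf("StabilityInterval: -delta_eps_u in (%.4f, %.4f)  [eta_u in (%.2f, %.2f)]\n",
              object@delta_eps_min, object@delta_eps_max,
              exp(object@delta_eps_min), exp(object@delta_eps_max)))
  cat(sprintf("  signal range used: [%g, %g]\n", object@s_min, object@s_max))
})

setMethod("show", "Tissue", function(object) {
  cat(sprintf("Tissue: %d cells, radius %.4g\n", nCells(object), object@radius))
})

setMethod("show", "CellGraph", function(object) {
  d <- object@distances
  finite <- d[is.finite(d)]
  cat(sprintf("CellGraph: %d cells, %d edges, mean degree %.2f, eccentricity <= %d\n",
              nCells(object), sum(object@adjacency) / 2L,
              mean(object@degrees), as.integer(max(finite))))
})

setMethod("show", "SignalKernel", function(object) {
  if (object@kind == "dispersion")
    cat(sprintf("SignalKernel: dispersion, q=%g, a=%.4g, %d cells\n",
                object@q, object@a, nrow(object@weights)))
  else
    cat(sprintf("SignalKernel: neighbor-mean, %d cells\n", nrow(object@weights)))
})

setMethod("show", "TissueState", function(object) {
  cat(sprintf("TissueState: %d cells, t=%.4g, %s (%d steps)\n",
              nCells(object), object@time,
              if (object@converged) "converged" else "NOT converged", object@steps))
  if (!all(is.na(object@labels))) {
    tab <- table(factor(object@labels, levels = c("u+v-", "u-v+", "undecided")))
    cat(sprintf("  fates: %d u+v-, %d u-v+, %d undecided\n", tab[1L], tab[2L], tab[3L]))
  }
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %d grid points over -delta_eps_u in [%.4f, %.4f]\n",
              length(object@neg_delta_eps), min(object@neg_delta_eps),
              max(object@neg_delta_eps)))
  print(as.data.frame(object))
})

setMethod("show", "PCFResult", function(object) {
  cat(sprintf("PCFResult: %d distances, %d u+v- and %d u-v+ of %d cells\n",
              length(object@k), object@n_u, object@n_v, object@n))
  print(as.data.frame(object))
})

#' @method as.data.frame SweepResult
#' @export
as.data.frame.SweepResult <- function(x, ...) {
  data.frame(neg_delta_eps = x@neg_delta_eps, prop_u = x@prop_u,
             prop_v = x@prop_v, count_u = x@count_u, count_v = x@count_v,
             converged = x@converged)
}
setMethod("as.data.frame", "SweepResult", as.data.frame.SweepResult)

#' @method as.data.frame PCFResult
#' @export
as.data.frame.PCFResult <- function(x, ...) {
  data.frame(k = x@k, pairs = x@pairs, pairs_u = x@pairs_u, pairs_v = x@pairs_v,
             rho_u = x@rho_u, rho_v = x@rho_v)
}
setMethod("as.data.frame", "PCFResult", as.data.frame.PCFResult)
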