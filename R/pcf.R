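#' Pair counts per graph distance
#'
#' Counts, for every observed hop distance k, the ordered cell pairs (i, j),
#' i != j, at distance k (|S_k|) and the same-type subsets |S^u_k| and
#' |S^v_k|. Ordered-pair semantics are used consistently across numerator
#' and denominator sets, so each unordered pair counts twice everywhere and
#' all derived ratios are unchanged. Distances with no pairs are omitted.
#'
#' @param labels per-cell fates, "u+v-" or "u-v+"; any "undecided" or NA
#'   label is rejected (with the offending cells listed).
#' @param distances hop-distance matrix (finite, e.g.
#'   [graphDistances()]).
#' @param ordered count ordered pairs (default); \code{FALSE} halves every
#'   count.
#' @return a [PCFResult-class] object with counts filled and correlations
#'   NA (see [pairCorrelation()]).
#' @export
pairCounts <- function(labels, distances, ordered = TRUE) {
  n <- length(labels)
  stopifnot(nrow(distances) == n, ncol(distances) == n)
  bad <- which(is.na(labels) | !labels %in% c("u+v-", "u-v+"))
  if (length(bad))
    stop("cells without a decided fate: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(distances)))
    stop("distances must be finite", call. = FALSE)
  # distances are integer hop counts, so per-k counting is a tabulate pass
  di <- matrix(as.integer(round(distances)), n, n)
  is_u <- labels == "u+v-"
  all_k <- tabulate(di, nbins = max(di))          # diagonal is 0: dropped
  uu <- tabulate(di[is_u, is_u, drop = FALSE], nbins = max(di))
  vv <- tabulate(di[!is_u, !is_u, drop = FALSE], nbins = max(di))
  ks <- which(all_k > 0L)
  pairs <- as.numeric(all_k[ks])
  pairs_u <- as.numeric(uu[ks])
  pairs_v <- as.numeric(vv[ks])
  if (!ordered) {
    pairs <- pairs / 2; pairs_u <- pairs_u / 2; pairs_v <- pairs_v / 2
  }
  m <- length(ks)
  new("PCFResult", k = as.integer(ks), pairs = pairs, pairs_u = pairs_u,
      pairs_v = pairs_v, rho_u = rep(NA_real_, m), rho_v = rep(NA_real_, m),
      n_u = sum(is_u), n_v = sum(!is_u), n = n)
}

#' Graph-distance pair correlation functions
#'
#' Normalizes the same-type pair proportions at each distance by the
#' probability of drawing two same-type cells at random without
#' replacement:
#' \deqn{\rho_u(k) = \frac{|S^u_k| / |S_k|}{|T^u|(|T^u|-1) / (N(N-1))}}
#' and analogously for \eqn{\rho_v}. Under uniformly random labeling with
#' fixed counts the expectation is exactly 1 at every distance; values
#' above/below 1 flag an excess/deficit of same-type pairs at that range.
#'
#' @inheritParams pairCounts
#' @return a [PCFResult-class] object with \code{rho_u}, \code{rho_v}
#'   filled.
#' @examples
#' g <- lineGraph(4)
#' pc <- pairCorrelation(c("u+v-", "u+v-", "u-v+", "u-v+"), graphDistances(g))
#' as.data.frame(pc)   # rho at distance 1 is 2
#' @export
pairCorrelation <- function(labels, distances) {
  res <- pairCounts(labels, distances, ordered = TRUE)
  if (res@n_u < 2L || res@n_v < 2L)
    stop(sprintf(paste0("normalization undefined: need at least 2 cells of ",
                        "each type (have %d u+v-, %d u-v+)"),
                 res@n_u, res@n_v), call. = FALSE)
  n <- res@n
  p_uu <- res@n_u * (res@n_u - 1) / (n * (n - 1))
  p_vv <- res@n_v * (res@n_v - 1) / (n * (n - 1))
  res@rho_u <- (res@pairs_u / res@pairs) / p_uu
  res@rho_v <- (res@pairs_v / res@pairs) / p_vv
  res
}
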