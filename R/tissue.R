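# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage sub-seed from a global seed (kept below 2^31).
.subSeed <- function(seed, stage) {
  stages <- c(tissue = 1, init = 2, labels = 3, retry = 4)
  as.integer((as.double(seed) * 48271 + 1299709 * stages[[stage]]) %% 2147483647)
}

#' Generate an irregular disc-shaped tissue
#'
#' Packs n equal-radius cells into a disc: seeded blue-noise (best-candidate)
#' sampling followed by short-range repulsion relaxation, which produces a
#' jammed but irregular packing whose pruned Delaunay contact graph has
#' about six contacts per bulk cell and three to four at the boundary. The
#' common cell radius is set to \code{contact_factor/2} times the median
#' nearest-neighbor spacing so relaxed neighbors touch. Regenerates with a
#' derived seed (bounded retries) if the contact graph comes out
#' disconnected.
#'
#' In an irregular (non-crystalline) packing the distances to touching
#' neighbors spread about 10 percent around the median nearest-neighbor
#' spacing, so the contact distance must sit above that spread: the default
#' \code{contact_factor = 1.3} retains the touching Delaunay neighbors
#' (bulk about six, boundary three to four) while still pruning the long
#' non-contact Delaunay edges.
#'
#' @param n number of cells (>= 2).
#' @param seed RNG seed; the same seed reproduces positions bit-for-bit.
#' @param contact_factor multiple of the median nearest-neighbor spacing
#'   that defines the contact distance 2*radius (default 1.3).
#' @param relax_iter relaxation iterations.
#' @param candidates candidates per best-candidate insertion.
#' @param max_retries connectivity retries before giving up.
#' @return a [Tissue-class] object.
#' @examples
#' tis <- discTissue(60, seed = 1)
#' g <- contactGraph(tis)
#' mean(cellDegrees(g))
#' @export
discTissue <- function(n, seed, contact_factor = 1.3, relax_iter = 160,
                       candidates = 16, max_retries = 5) {
  stopifnot(n >= 2)
  for (attempt in 0:max_retries) {
    s <- if (attempt == 0) as.integer(seed) else
      .subSeed(as.double(seed) + attempt, "retry")
    pts <- .withSeed(s, .packDisc(n, candidates, relax_iter))
    nn <- apply(as.matrix(stats::dist(pts)) + diag(Inf, n), 1, min)
    tissue <- new("Tissue", positions = pts,
                  radius = contact_factor * stats::median(nn) / 2)
    g <- contactGraph(tissue)
    if (all(is.finite(g@distances))) return(tissue)
  }
  stop(sprintf(paste0("disc tissue generation failed: contact graph still ",
                      "disconnected after %d retries (n=%d, seed=%s); ",
                      "try a larger contact_factor"),
               max_retries, n, format(seed)), call. = FALSE)
}

# Blue-noise sample + short-range repulsive relaxation inside the unit disc.
# Relaxation applies compressive spring forces along current Delaunay edges
# with a rest length slightly above the hexagonal-packing spacing, so the
# packing jams into an irregular but locally even arrangement; points pushed
# past the disc boundary are projected back onto it.
.packDisc <- function(n, candidates, relax_iter) {
  runif_disc <- function(k) {
    r <- sqrt(stats::runif(k)); th <- 2 * pi * stats::runif(k)
    cbind(r * cos(th), r * sin(th))
  }
  pts <- matrix(0, n, 2)
  pts[1L, ] <- runif_disc(1L)
  for (i in 2:n) {
    cand <- runif_disc(candidates)
    prev <- pts[seq_len(i - 1L), , drop = FALSE]
    d2min <- apply(cand, 1, function(p)
      min((prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2))
    pts[i, ] <- cand[which.max(d2min), ]
  }
  h <- sqrt(2 * pi / (sqrt(3) * n))   # hexagonal packing spacing in unit disc
  rest <- 1.25 * h                    # slight over-pressure jams the packing
  step <- 0.2
  ed <- .delaunayEdges(pts)
  for (iter in seq_len(relax_iter)) {
    if (iter %% 5L == 0L) ed <- .delaunayEdges(pts)
    vx <- pts[ed[, 1], 1] - pts[ed[, 2], 1]
    vy <- pts[ed[, 1], 2] - pts[ed[, 2], 2]
    len <- sqrt(vx^2 + vy^2)
    f <- pmax(rest - len, 0) / len    # repulsive only, as in truss smoothing
    fx <- f * vx; fy <- f * vy
    ii <- c(ed[, 1], ed[, 2])
    dxv <- dyv <- numeric(n)
    sx <- tapply(c(fx, -fx), ii, sum); sy <- tapply(c(fy, -fy), ii, sum)
    at <- as.integer(names(sx))
    dxv[at] <- sx; dyv[at] <- sy
    pts[, 1] <- pts[, 1] + step * dxv
    pts[, 2] <- pts[, 2] + step * dyv
    rad <- sqrt(rowSums(pts^2))
    out <- rad > 1
    if (any(out)) pts[out, ] <- pts[out, ] / rad[out]
  }
  pts
}

#' Build the cell contact graph of a tissue
#'
#' Initializes the graph from the Delaunay triangulation of the cell
#' centroids and removes every edge whose Euclidean length exceeds the sum
#' of the two cell radii (2 * radius), so only touching cells stay
#' connected. Hop distances are unweighted shortest paths; unreachable pairs
#' are Inf. Fewer than three non-collinear points fall back to the
#' complete-graph-then-prune construction.
#'
#' @param tissue a [Tissue-class] object.
#' @return a [CellGraph-class] object.
#' @export
contactGraph <- function(tissue) {
  stopifnot(is(tissue, "Tissue"))
  pts <- tissue@positions
  n <- nrow(pts)
  cutoff <- 2 * tissue@radius
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  collinear <- n < 3L || sv[2] < 1e-10 * max(sv[1], 1)
  adj <- matrix(FALSE, n, n)
  if (collinear) {
    d <- as.matrix(stats::dist(pts))
    adj <- d <= cutoff
    diag(adj) <- FALSE
  } else {
    ed <- .delaunayEdges(pts)
    len <- sqrt((pts[ed[, 1], 1] - pts[ed[, 2], 1])^2 +
                  (pts[ed[, 1], 2] - pts[ed[, 2], 2])^2)
    ed <- ed[len <= cutoff, , drop = FALSE]
    adj[ed] <- TRUE
    adj[ed[, c(2, 1), drop = FALSE]] <- TRUE
  }
  .cellGraphFromAdjacency(adj)
}

.cellGraphFromAdjacency <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(g)
  dimnames(d) <- NULL
  new("CellGraph", adjacency = adj, distances = d,
      degrees = as.integer(rowSums(adj)))
}

#' Ideal hexagonal lattice fixture
#'
#' Triangular-lattice packing with unit spacing in which (with
#' \code{periodic = TRUE}) every cell has exactly six neighbors. Adjacency
#' is constructed combinatorially (odd-row offset layout), so regular-grid
#' degeneracies of the Delaunay triangulation never arise. Wrapped
#' neighbors that coincide on small tori are deduplicated to simple-graph
#' edges; self-loops are dropped.
#'
#' @param rows,cols lattice dimensions (>= 2). Periodic wrapping requires an
#'   even number of rows (an odd count breaks the row-offset regularity).
#' @param periodic wrap both directions into a torus.
#' @return list with elements \code{tissue} ([Tissue-class], planar
#'   embedding; for tori the coordinates are for display only) and
#'   \code{graph} ([CellGraph-class]).
#' @examples
#' hex <- hexLattice(6, 6, periodic = TRUE)
#' all(cellDegrees(hex$graph) == 6)
#' @export
hexLattice <- function(rows, cols, periodic = FALSE) {
  stopifnot(rows >= 2, cols >= 2)
  if (periodic && rows %% 2 == 1)
    stop("periodic hex lattice requires an even number of rows", call. = FALSE)
  idx <- function(r, c) r * cols + c + 1L
  pos <- matrix(0, rows * cols, 2)
  for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
    pos[idx(r, c), ] <- c(c + (r %% 2) / 2, r * sqrt(3) / 2)
  }
  n <- rows * cols
  adj <- matrix(FALSE, n, n)
  for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
    shift <- if (r %% 2 == 0) -1L else 1L
    nb <- rbind(c(r, c - 1), c(r, c + 1),
                c(r - 1, c), c(r + 1, c),
                c(r - 1, c + shift), c(r + 1, c + shift))
    for (k in seq_len(nrow(nb))) {
      rr <- nb[k, 1]; cc <- nb[k, 2]
      if (periodic) { rr <- rr %% rows; cc <- cc %% cols }
      if (rr < 0 || rr >= rows || cc < 0 || cc >= cols) next
      j <- idx(rr, cc); i <- idx(r, c)
      if (i != j) { adj[i, j] <- TRUE; adj[j, i] <- TRUE }
    }
  }
  list(tissue = new("Tissue", positions = pos, radius = 0.525),
       graph = .cellGraphFromAdjacency(adj))
}

#' One-dimensional chain of cells
#'
#' Path graph on n cells: d_ij = |i - j|.
#'
#' @param n number of cells (>= 2).
#' @return a [CellGraph-class] object.
#' @export
lineGraph <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n)
  d <- abs(outer(i, i, "-"))
  adj <- d == 1L
  new("CellGraph", adjacency = adj, distances = d + 0,
      degrees = as.integer(rowSums(adj)))
}

# planar embedding for the line fixture (used for CSV export)
.lineTissue <- function(n) {
  new("Tissue", positions = cbind(as.numeric(seq_len(n)), 0), radius = 0.525)
}
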