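# Internal Bowyer-Watson Delaunay triangulation.
#
# Incremental insertion with a super-triangle; triangles carry cached
# circumcircle data so the bad-triangle search is a vectorized comparison.
# Intended for the tissue scales of this package (hundreds of cells);
# degenerate (collinear) point sets are handled by the caller.

.circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14 * max(1, abs(ax) + abs(ay) + abs(bx) + abs(by))) {
    return(c(Inf, Inf, Inf))   # collinear: infinite circumcircle
  }
  a2 <- ax * ax + ay * ay; b2 <- bx * bx + by * by; c2 <- cx * cx + cy * cy
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

# Returns a 2-column integer matrix of undirected Delaunay edges (i < j).
.delaunayEdges <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (n == 2L) return(matrix(c(1L, 2L), ncol = 2))
  ctr <- colMeans(pts)
  span <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2)), 1e-9)
  m <- 50 * span
  sup <- rbind(ctr + c(-3 * m, -m), ctr + c(3 * m, -m), ctr + c(0, 3 * m))
  all_pts <- rbind(pts, sup)

  cap <- 4L * n + 16L
  tri <- matrix(NA_integer_, cap, 3)
  ccx <- ccy <- cr2 <- rep(NA_real_, cap)
  alive <- rep(FALSE, cap)
  tri[1L, ] <- c(n + 1L, n + 2L, n + 3L)
  cc <- .circumcircle(sup[1, 1], sup[1, 2], sup[2, 1], sup[2, 2], sup[3, 1], sup[3, 2])
  ccx[1L] <- cc[1]; ccy[1L] <- cc[2]; cr2[1L] <- cc[3]
  alive[1L] <- TRUE
  ntri <- 1L

  grow <- function() {
    cap2 <- 2L * cap
    tri <<- rbind(tri, matrix(NA_integer_, cap2 - cap, 3))
    ccx <<- c(ccx, rep(NA_real_, cap2 - cap))
    ccy <<- c(ccy, rep(NA_real_, cap2 - cap))
    cr2 <<- c(cr2, rep(NA_real_, cap2 - cap))
    alive <<- c(alive, rep(FALSE, cap2 - cap))
    cap <<- cap2
  }

  for (p in seq_len(n)) {
    px <- pts[p, 1]; py <- pts[p, 2]
    idx <- which(alive[seq_len(ntri)])
    bad <- idx[(px - ccx[idx])^2 + (py - ccy[idx])^2 <= cr2[idx] * (1 + 1e-12)]
    # polygon boundary = edges of bad triangles appearing exactly once
    e <- rbind(tri[bad, c(1, 2), drop = FALSE],
               tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(1, 3), drop = FALSE])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- e[, 1] * (n + 4) + e[, 2]
    once <- !(key %in% key[duplicated(key)])
    poly <- e[once, , drop = FALSE]
    alive[bad] <- FALSE
    for (r in seq_len(nrow(poly))) {
      a <- poly[r, 1]; b <- poly[r, 2]
      cc <- .circumcircle(all_pts[a, 1], all_pts[a, 2],
                          all_pts[b, 1], all_pts[b, 2], px, py)
      if (ntri + 1L > cap) grow()
      ntri <- ntri + 1L
      tri[ntri, ] <- c(a, b, p)
      ccx[ntri] <- cc[1]; ccy[ntri] <- cc[2]; cr2[ntri] <- cc[3]
      alive[ntri] <- TRUE
    }
  }

  keep <- alive[seq_len(ntri)] & apply(tri[seq_len(ntri), , drop = FALSE] <= n, 1, all)
  tt <- tri[seq_len(ntri), , drop = FALSE][keep, , drop = FALSE]
  if (nrow(tt) == 0L) stop("triangulation failed (degenerate input?)", call. = FALSE)
  e <- rbind(tt[, c(1, 2)], tt[, c(2, 3)], tt[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}
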