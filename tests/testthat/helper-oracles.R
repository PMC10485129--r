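# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: probabilities are rebuilt summand by summand,
# the triangulation by empty-circumcircle enumeration, Jacobians by finite
# differences, pair counts by a double loop.

# Term-by-term enumeration of the seven Boltzmann binding configurations.
# Each configuration contributes weight = product of the per-species etas,
# the interaction eta and the concentrations of whatever is bound.
oracle_binding <- function(u, v, s, p) {
  w <- c(
    u_only = p@eta_u * u,
    v_only = p@eta_v * v,
    s_only = p@eta_s * s,
    uv = p@eta_u * p@eta_v * p@eta_uv * u * v,
    us = p@eta_u * p@eta_s * p@eta_us * u * s,
    vs = p@eta_v * p@eta_s * p@eta_vs * v * s,
    uvs = p@eta_u * p@eta_v * p@eta_s * p@eta_uvs * u * v * s)
  z <- 1 + sum(w)          # empty configuration + the seven bound ones
  # u's promoter is productive in every configuration with u bound, and
  # likewise for v; the lone signal-bound state is productive for neither
  list(p_u = (w[["u_only"]] + w[["uv"]] + w[["us"]] + w[["uvs"]]) / z,
       p_v = (w[["v_only"]] + w[["uv"]] + w[["vs"]] + w[["uvs"]]) / z)
}

# Brute-force Delaunay edges: a triangle belongs to the triangulation iff
# its circumcircle contains no other point; edges are the union over such
# triangles. O(n^4), for small n only.
oracle_delaunay <- function(pts) {
  n <- nrow(pts)
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[j, 1]; by <- pts[j, 2]
    cx <- pts[k, 1]; cy <- pts[k, 2]
    dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(dd) < 1e-12) next
    a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
    ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / dd
    uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / dd
    r2 <- (ux - ax)^2 + (uy - ay)^2
    others <- setdiff(1:n, c(i, j, k))
    if (all((pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2 >
              r2 * (1 - 1e-12)))
      edges <- rbind(edges, c(i, j), c(j, k), c(i, k))
  }
  unique(cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
}

edge_key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))

# Central finite differences of the tissue right-hand side.
oracle_jacobian_fd <- function(u, v, kernel, params, h = 1e-7) {
  n <- length(u)
  f <- function(x) {
    uu <- x[1:n]; vv <- x[(n + 1):(2 * n)]
    s <- receivedSignal(kernel, uu)
    r <- grnRHS(uu, vv, s, params)
    c(r$du, r$dv)
  }
  x0 <- c(u, v)
  J <- matrix(0, 2 * n, 2 * n)
  for (j in seq_len(2 * n)) {
    e <- numeric(2 * n); e[j] <- h
    J[, j] <- (f(x0 + e) - f(x0 - e)) / (2 * h)
  }
  J
}

# Double-loop ordered pair counts per distance.
oracle_pair_counts <- function(labels, d) {
  ks <- sort(unique(d[d > 0 & row(d) != col(d)]))
  out <- data.frame(k = ks, pairs = 0, pairs_u = 0, pairs_v = 0)
  n <- length(labels)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    row <- match(d[i, j], ks)
    out$pairs[row] <- out$pairs[row] + 1
    if (labels[i] == "u+v-" && labels[j] == "u+v-")
      out$pairs_u[row] <- out$pairs_u[row] + 1
    if (labels[i] == "u-v+" && labels[j] == "u-v+")
      out$pairs_v[row] <- out$pairs_v[row] + 1
  }
  out
}

# Single cell at a fixed external signal, integrated with plain Euler via
# the package's rhs (used as the fate-switching oracle).
single_cell_fate <- function(params, s, u0 = 1e-3, v0 = 1e-3,
                             dt = 0.01, t_end = 500) {
  u <- u0; v <- v0
  for (i in seq_len(t_end / dt)) {
    r <- grnRHS(u, v, s, params)
    u <- max(u + dt * r$du, 0)
    v <- max(v + dt * r$dv, 0)
  }
  c(u = u, v = v)
}

# small disc fixture shared by several files (cached per session)
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tis <- discTissue(60, seed = 11)
      g <- contactGraph(tis)
      cache <<- list(tissue = tis, graph = g)
    }
    cache
  }
})
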