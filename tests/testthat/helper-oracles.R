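# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# Exact minimum path cover of an undirected graph by subset DP over
# (covered set, open path end).  Feasible up to ~12 nodes.
min_path_cover_exact <- function(n, edges) {
  if (n == 0L) return(0L)
  adjbit <- integer(n)
  if (length(edges)) {
    edges <- matrix(edges, ncol = 2)
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      adjbit[a] <- bitwOr(adjbit[a], bitwShiftL(1L, b - 1L))
      adjbit[b] <- bitwOr(adjbit[b], bitwShiftL(1L, a - 1L))
    }
  }
  full <- bitwShiftL(1L, n) - 1L
  INF <- 1000L
  # dp[mask + 1, last + 1]: min paths covering `mask`, current path open
  # at `last` (0 = no open path)
  dp <- matrix(INF, full + 1L, n + 1L)
  dp[1L, 1L] <- 0L
  bits <- bitwShiftL(1L, 0:(n - 1L))
  for (mask in 0:(full - 1L)) {
    row <- dp[mask + 1L, ]
    if (all(row >= INF)) next
    unset <- which(bitwAnd(mask, bits) == 0L)
    for (last in which(row < INF) - 1L) {
      cost <- row[last + 1L]
      for (v in unset) {
        nm <- bitwOr(mask, bits[v]) + 1L
        # start a new path at v
        if (cost + 1L < dp[nm, v + 1L]) dp[nm, v + 1L] <- cost + 1L
        # or extend the open path along an edge last-v
        if (last > 0L && bitwAnd(adjbit[last], bits[v]) != 0L &&
            cost < dp[nm, v + 1L]) dp[nm, v + 1L] <- cost
      }
    }
  }
  min(dp[full + 1L, -1L])
}

# winding-number point-in-polygon (different method from the package's
# ray caster); poly open n x 2
winding_inside <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(i) {
    ang <- atan2(poly[, 2] - py[i], poly[, 1] - px[i])
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi
  }, logical(1))
}

# brute-force area of a polygon footprint by rasterization
raster_area <- function(poly, xlim, ylim, nstep = 200L) {
  gx <- seq(xlim[1], xlim[2], length.out = nstep)
  gy <- seq(ylim[1], ylim[2], length.out = nstep)
  cell <- diff(gx[1:2]) * diff(gy[1:2])
  px <- rep(gx, times = nstep); py <- rep(gy, each = nstep)
  sum(winding_inside(px, py, poly)) * cell
}

# random valid voxel spec
random_voxel <- function() {
  L1 <- runif(1, 0.5, 3); L2 <- runif(1, 0.5, 3)
  voxel_spec(w1 = runif(1, 0.05, 1) * L2, w2 = runif(1, 0.05, 1) * L1,
             h1 = runif(1, 0.1, 1.5), h2 = runif(1, 0.1, 1.5),
             L1 = L1, L2 = L2,
             E1 = runif(1, 5, 600), E2 = runif(1, 5, 600))
}

swap_voxel <- function(v) {
  voxel_spec(w1 = v$w2, w2 = v$w1, h1 = v$h2, h2 = v$h1,
             L1 = v$L2, L2 = v$L1, E1 = v$E2, E2 = v$E1)
}

# small connected waypoint graphs (<= `max_nodes`) drawn from the
# package generator; returns list(graph, components as node subsets)
small_test_graph <- function(seed, max_nodes = 12L) {
  f <- langer_field(2, 1, "random", seed = seed, unit_size = 10)
  generate_grid_lines(f, spacing = 10, waypoints_per_unit = max_nodes %/% 2L)
}

graph_components <- function(graph) {
  n <- length(graph$x)
  comp <- integer(n)
  adj <- vector("list", n)
  if (nrow(graph$edges)) {
    for (r in seq_len(nrow(graph$edges))) {
      a <- graph$edges[r, 1]; b <- graph$edges[r, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]])
    }
  }
  split(seq_len(n), comp)
}

# induced subgraph as (n, edges) with nodes relabelled 1..k
induced_subgraph <- function(graph, nodes) {
  remap <- integer(length(graph$x))
  remap[nodes] <- seq_along(nodes)
  e <- graph$edges
  keep <- e[, 1] %in% nodes & e[, 2] %in% nodes
  list(n = length(nodes),
       edges = cbind(remap[e[keep, 1]], remap[e[keep, 2]]))
}
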