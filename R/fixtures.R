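# Seeded synthetic-data generators: every pipeline stage is testable
# without external data.

#' Hyperbolic-paraboloid surface mesh
#'
#' Triangulated saddle surface z = curvature * (x^2 - y^2) on a square
#' footprint centred at the origin, the shape family of the
#' cricothyrotomy training puck substrate.  A `resolution` x `resolution`
#' vertex grid gives `resolution^2` vertices and
#' `2 (resolution - 1)^2` triangles.
#'
#' @param extent side length of the square footprint, mm (default 40).
#' @param curvature saddle coefficient, 1/mm (default 0.01; 0 gives a
#'   flat plate).
#' @param resolution vertices per side (>= 2, default 41).
#' @return A [tri_mesh()] with upward (outward, +z) normals.
#' @export
make_paraboloid <- function(extent = 40, curvature = 0.01, resolution = 41L) {
  ap_check(resolution >= 2, "make_paraboloid: `resolution` must be >= 2")
  g <- seq(-extent / 2, extent / 2, length.out = resolution)
  verts <- cbind(x = rep(g, times = resolution),
                 y = rep(g, each = resolution),
                 z = 0)
  verts[, 3] <- curvature * (verts[, 1]^2 - verts[, 2]^2)
  faces <- grid_faces(resolution, resolution)
  tri_mesh(verts, faces)
}

# CCW (viewed from +z) triangulation of an nx x ny vertex grid laid out
# x-fastest
grid_faces <- function(nx, ny) {
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- (j - 1) * nx + i
  v10 <- v00 + 1
  v01 <- v00 + nx
  v11 <- v01 + 1
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

#' Closed hyperbolic-paraboloid puck mesh
#'
#' The saddle surface of [make_paraboloid()] extruded vertically by
#' `thickness` and closed with side walls, producing a solid suitable
#' for contour extraction.
#'
#' @inheritParams make_paraboloid
#' @param thickness vertical extrusion, mm (default 6).
#' @return A [tri_mesh()].
#' @export
make_paraboloid_puck <- function(extent = 40, curvature = 0.01,
                                 thickness = 6, resolution = 21L) {
  bottom <- make_paraboloid(extent, curvature, resolution)
  nv <- nrow(bottom$vertices)
  top_v <- bottom$vertices
  top_v[, 3] <- top_v[, 3] + thickness
  verts <- rbind(bottom$vertices, top_v)
  faces_bottom <- bottom$faces[, c(1, 3, 2)]  # flip: normals face down
  faces_top <- bottom$faces + nv
  # side walls: stitch the boundary loop
  n <- resolution
  ring <- c(seq_len(n),                       # bottom edge (y = min)
            seq(2L * n, n * n, by = n),       # right edge
            seq(n * n - 1L, n * (n - 1L) + 1L, by = -1L),  # top edge
            seq(n * (n - 2L) + 1L, n + 1L, by = -n))       # left edge
  m <- length(ring)
  nxt <- c(ring[-1], ring[1])
  walls <- rbind(cbind(ring, nxt, nxt + nv), cbind(ring, nxt + nv, ring + nv))
  tri_mesh(verts, rbind(faces_bottom, faces_top, walls))
}

#' Inclined-plane mesh
#'
#' A square plate of gradient tan(alpha) along +x, emulating an
#' adjustable inclined deposition platform.
#'
#' @param alpha inclination, degrees.
#' @param extent side length, mm (default 40).
#' @param resolution vertices per side (default 11).
#' @return A [tri_mesh()].
#' @export
make_incline <- function(alpha, extent = 40, resolution = 11L) {
  g <- seq(0, extent, length.out = resolution)
  verts <- cbind(x = rep(g, times = resolution),
                 y = rep(g, each = resolution),
                 z = rep(g, times = resolution) * tan(alpha * pi / 180))
  tri_mesh(verts, grid_faces(resolution, resolution))
}

#' Synthetic stress-strain curve
#'
#' Generates `stress = E * strain` (linear) or `E * strain + 0.5 * E2q *
#' strain^2` (quadratic) on `n` points over `strain_max`, with optional
#' additive zero-mean Gaussian noise on the stress.
#'
#' @param E small-strain modulus, kPa.
#' @param model `"linear"` or `"quadratic"`.
#' @param noise_sd stress noise SD, kPa (default 0).
#' @param n number of points (default 100).
#' @param seed RNG seed (caller's RNG state untouched).
#' @param strain_max maximum strain (default 0.4).
#' @param E2q quadratic stiffening coefficient, kPa (default `3 * E`).
#' @return Data frame with columns `strain`, `stress`.
#' @export
make_stress_strain <- function(E, model = c("linear", "quadratic"),
                               noise_sd = 0, n = 100L, seed = 1L,
                               strain_max = 0.4, E2q = 3 * E) {
  model <- match.arg(model)
  eps <- seq(0, strain_max, length.out = n)
  sig <- if (model == "linear") E * eps else E * eps + 0.5 * E2q * eps^2
  if (noise_sd > 0)
    sig <- sig + ap_with_seed(seed, stats::rnorm(n, 0, noise_sd))
  data.frame(strain = eps, stress = sig)
}

#' Synthetic spanning-width measurement table
#'
#' Samples the quadratic narrowing surface `w1/w0 = c0 + c1 x + c2 y +
#' c3 x^2 + c4 xy + c5 y^2` (x = h/d, y = s/d) at `n` quasi-random design
#' points, adds optional Gaussian noise, and clamps to [0, 1] only when
#' noise is present (noise-free tables reproduce the surface exactly).
#'
#' The default coefficients emulate the observed behaviour: narrowing
#' worsens at low print heights and wide spacings.
#'
#' @param true_coeffs length-6 coefficient vector (default
#'   `c(0.30, 1.1, -0.35, -0.35, 0.1, 0.02)`).
#' @param noise_sd measurement noise SD (default 0).
#' @param n number of measurement points (default 36).
#' @param seed RNG seed.
#' @return Data frame with columns `h_over_d`, `s_over_d`, `w_ratio`.
#' @export
make_spanning_table <- function(true_coeffs = c(0.30, 1.1, -0.35, -0.35, 0.1, 0.02),
                                noise_sd = 0, n = 36L, seed = 1L) {
  ap_check(length(true_coeffs) == 6, "make_spanning_table: need 6 coefficients")
  k <- ceiling(sqrt(n))
  grid <- expand.grid(h_over_d = seq(0.3, 1.2, length.out = k),
                      s_over_d = seq(0.1, 1.0, length.out = k))
  grid <- grid[seq_len(n), ]
  cf <- true_coeffs
  w <- cf[1] + cf[2] * grid$h_over_d + cf[3] * grid$s_over_d +
    cf[4] * grid$h_over_d^2 + cf[5] * grid$h_over_d * grid$s_over_d +
    cf[6] * grid$s_over_d^2
  if (noise_sd > 0) {
    w <- w + ap_with_seed(seed, stats::rnorm(n, 0, noise_sd))
    w <- pmin(1, pmax(0, w))
  }
  data.frame(h_over_d = grid$h_over_d, s_over_d = grid$s_over_d, w_ratio = w)
}

#' Synthetic capsule compression trace
#'
#' Zero (noisy) force while the plates close on free fluid, then a
#' linear force ramp once the plates touch the capsule at gap
#' `diameter`.
#'
#' @param diameter capsule diameter, mm.
#' @param gap_max starting gap, mm (default 1.2).
#' @param step gap decrement per sample, mm (default 0.005).
#' @param stiffness force ramp slope, N/mm (default 2).
#' @param noise_sd force noise SD, N (default 0).
#' @param seed RNG seed.
#' @return Data frame with columns `gap`, `force`.
#' @export
make_compression_trace <- function(diameter, gap_max = 1.2, step = 0.005,
                                   stiffness = 2, noise_sd = 0, seed = 1L) {
  gap <- seq(gap_max, 0.05, by = -step)
  force <- pmax(0, diameter - gap) * stiffness
  if (noise_sd > 0)
    force <- force + ap_with_seed(seed, stats::rnorm(length(gap), 0, noise_sd))
  data.frame(gap = gap, force = force)
}

#' Toolpath-optimization benchmark harness
#'
#' For each grid size and replicate: draw a random orientation field,
#' build the waypoint graph (10 waypoints per unit by default), take the
#' naive per-unit decomposition and the DFS-optimized one, and record
#' the continuity metrics.
#'
#' @param grid_sizes vector of square grid edge lengths in units
#'   (default `c(4, 6, 8, 10, 12)`).
#' @param reps replicates per size (default 5).
#' @param seed master seed; replicate r of size g uses a seed derived
#'   deterministically from it.
#' @param restarts optimizer restarts (default 100).
#' @param waypoints_per_unit waypoints per grid unit (default 10).
#' @param unit_size grid unit side, mm (default 10).
#' @param spacing print-line spacing, mm; the default equals `unit_size`,
#'   the coarse benchmark abstraction in which each grid unit holds a
#'   single 10-waypoint print line (the per-unit naive path).
#' @return Data frame with one row per (size, rep): `grid_size`, `rep`,
#'   `n_units`, `naive_n_paths`, `n_paths`, `reduction_pct`,
#'   `coverage_pct`.
#' @export
make_benchmark_suite <- function(grid_sizes = c(4, 6, 8, 10, 12), reps = 5L,
                                 seed = 1L, restarts = 100L,
                                 waypoints_per_unit = 10L, unit_size = 10,
                                 spacing = unit_size) {
  rows <- list()
  for (gi in seq_along(grid_sizes)) {
    g <- grid_sizes[gi]
    for (r in seq_len(reps)) {
      sub_seed <- (seed * 1000L + gi * 100L + r) %% .Machine$integer.max
      field <- langer_field(g, g, "random", seed = sub_seed,
                            unit_size = unit_size)
      graph <- generate_grid_lines(field, spacing = spacing,
                                   waypoints_per_unit = waypoints_per_unit)
      opt <- optimize_paths(graph, restarts = restarts, seed = sub_seed + 1L)
      met <- path_metrics(opt, graph,
                          baseline_unit_waypoints = waypoints_per_unit)
      rows[[length(rows) + 1L]] <- data.frame(
        grid_size = g, rep = r, n_units = g * g,
        naive_n_paths = met$naive_n_paths, n_paths = met$n_paths,
        reduction_pct = met$reduction_pct, coverage_pct = met$coverage_pct)
    }
  }
  do.call(rbind, rows)
}
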