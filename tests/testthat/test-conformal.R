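# Reorientation, segmentation, conformal layers, projection, gradients,
# and the inclination compensation.

flat_plate <- function(nx = 12, extent = 20, thickness = 0.5) {
  g <- seq(0, extent, length.out = nx)
  bot <- cbind(rep(g, nx), rep(g, each = nx), 0)
  top <- bot; top[, 3] <- thickness
  f <- anisoprint:::grid_faces(nx, nx)
  tri_mesh(rbind(bot, top), rbind(f[, c(1, 3, 2)], f + nx * nx))
}

test_that("a tilted plate is reoriented back to its thickness", {
  m <- flat_plate()
  R <- anisoprint:::rot_x(30)
  mt <- m
  mt$vertices <- m$vertices %*% t(R)
  mt$normals <- m$normals %*% t(R)
  ro <- reorient_min_height(mt)
  expect_lt(ro$z_extent, 0.5 + 1e-6)
  # idempotent on its own output
  ro2 <- reorient_min_height(ro$mesh)
  expect_equal(ro2$tilt_x, 0)
  expect_equal(ro2$tilt_y, 0)
  expect_equal(ro2$z_extent, ro$z_extent)
})

test_that("reorientation never increases the Z-extent", {
  set.seed(41)
  for (i in 1:5) {
    v <- matrix(rnorm(30), ncol = 3)
    m <- tri_mesh(v, matrix(c(1:9, 10, 1, 5), ncol = 3, byrow = TRUE))
    ro <- reorient_min_height(m)
    expect_lte(ro$z_extent, diff(range(m$vertices[, 3])) + 1e-9)
  }
})

test_that("normal-based segmentation matches a per-vertex brute-force check", {
  m <- make_paraboloid(20, 0.02, 15)
  sp <- suppressWarnings(split_top_bottom(m, nz_threshold = 0.5))
  ref_bottom <- which(m$normals[, 3] < 0.5 & abs(m$normals[, 3]) >= 1e-6)
  expect_equal(sp$bottom$vertex_idx, ref_bottom)
  expect_equal(sort(c(sp$bottom$vertex_idx, sp$top$vertex_idx)),
               seq_len(nrow(m$vertices)))
  # faces by majority vote
  votes <- matrix(seq_len(nrow(m$vertices)) %in% ref_bottom, ncol = 1)[m$faces]
  expect_equal(sp$bottom$face_idx,
               which(rowSums(matrix(votes, ncol = 3)) >= 2))
})

test_that("vertical side walls are counted in a warning", {
  # an open vertical band: every vertex normal is horizontal
  ring <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  verts <- rbind(cbind(ring, 0), cbind(ring, 2))
  nxt <- c(2:4, 1)
  faces <- rbind(cbind(1:4, nxt, nxt + 4), cbind(1:4, nxt + 4, 1:4 + 4))
  m <- tri_mesh(verts, faces)
  expect_warning(split_top_bottom(m), "near-vertical")
  sp <- suppressWarnings(split_top_bottom(m))
  expect_equal(sp$n_wall, 8)
  # wall vertices land in the top set by convention
  expect_length(sp$bottom$vertex_idx, 0)
})

test_that("linear fields interpolate exactly onto the grid", {
  set.seed(42)
  pts <- cbind(runif(40) * 10, runif(40) * 10, 0)
  pts[, 3] <- 2 * pts[, 1] + 3 * pts[, 2]
  hf <- heightfield_from_points(pts, 0.5)
  ref <- outer(hf$y, hf$x, function(Y, X) 2 * X + 3 * Y)
  expect_lt(max(abs(hf$z - ref), na.rm = TRUE), 1e-9)
  expect_error(heightfield_from_points(pts, 0), "spacing")
  collinear <- cbind(1:5, 2 * (1:5), 0)
  expect_error(heightfield_from_points(collinear, 0.5), "collinear|degenerate")
})

test_that("curved surfaces interpolate within the second-order bound", {
  g <- expand.grid(x = seq(-10, 10, by = 1), y = seq(-10, 10, by = 1))
  pts <- cbind(g$x, g$y, 0.01 * (g$x^2 - g$y^2))
  hf <- heightfield_from_points(pts, 0.25)
  ref <- outer(hf$y, hf$x, function(Y, X) 0.01 * (X^2 - Y^2))
  # max error of piecewise-linear interpolation <= h^2/8 * max |f''|
  expect_lt(max(abs(hf$z - ref), na.rm = TRUE), 0.02 * 1^2 / 8 + 1e-9)
})

test_that("conformal layers are cumulative vertical offsets with roles kept", {
  hf <- heightfield_from_function(function(x, y) 0 * x, c(0, 10), c(0, 10), 1)
  plan <- data.frame(role = "infill", thickness = 0.42)[rep(1, 3), ]
  ls <- conformal_layers(hf, plan)
  expect_equal(vapply(ls, `[[`, numeric(1), "offset"), c(0.42, 0.84, 1.26))

  # cric-style stack: 600 um covers around infill
  plan2 <- data.frame(role = c("bottom_cover", "infill", "infill", "top_cover"),
                      thickness = c(0.6, 0.84, 0.42, 0.6))
  ls2 <- conformal_layers(hf, plan2)
  expect_equal(vapply(ls2, `[[`, numeric(1), "offset"), cumsum(plan2$thickness))
  expect_equal(vapply(ls2, `[[`, character(1), "role"), plan2$role)
  expect_error(conformal_layers(hf, plan2[0, ]), "empty")

  # curved base: every layer is a pure vertical translation
  hf2 <- heightfield_from_function(function(x, y) 0.02 * x^2, c(0, 10), c(0, 10), 0.5)
  l <- conformal_layers(hf2, plan)[[2]]
  px <- runif(20, 0, 10); py <- runif(20, 0, 10)
  expect_equal(anisoprint:::layer_z(l, px, py) -
                 anisoprint:::sample_heightfield(hf2, px, py),
               rep(0.84, 20))
})

test_that("conformal layering commutes with rigid XY translation of the base", {
  f <- function(x, y) 0.01 * (x^2 - y^2)
  hf <- heightfield_from_function(f, c(0, 10), c(0, 10), 0.5)
  hft <- heightfield_from_function(function(x, y) f(x - 5, y - 7),
                                   c(5, 15), c(7, 17), 0.5)
  plan <- data.frame(role = "infill", thickness = 0.42)
  l <- conformal_layers(hf, plan)[[1]]
  lt <- conformal_layers(hft, plan)[[1]]
  px <- runif(20, 1, 9); py <- runif(20, 1, 9)
  expect_equal(anisoprint:::layer_z(lt, px + 5, py + 7),
               anisoprint:::layer_z(l, px, py), tolerance = 1e-9)
})

test_that("layer contours bound the footprint", {
  # extruded square: mid-height contour is the square outline
  m <- make_paraboloid_puck(extent = 20, curvature = 0, thickness = 2,
                            resolution = 8)
  cont <- layer_contour(m, 1)
  expect_length(cont, 1)
  expect_equal(anisoprint:::polygon_area(cont[[1]]), 400, tolerance = 1e-6)

  # saddle puck: contour area matches brute-force rasterization within 1%
  pk <- make_paraboloid_puck(extent = 30, curvature = 0.01, thickness = 4,
                             resolution = 16)
  sp <- suppressWarnings(split_top_bottom(pk))
  hf <- heightfield_from_points(pk$vertices[sp$bottom$vertex_idx, ], 1)
  layer <- conformal_layers(hf, data.frame(role = "infill", thickness = 2))[[1]]
  cont2 <- layer_contour(pk, layer)
  expect_length(cont2, 1)
  area <- anisoprint:::polygon_area(cont2[[1]])
  ref <- raster_area(cont2[[1]], c(-16, 16), c(-16, 16))
  expect_lt(abs(area - ref) / ref, 0.01)
  expect_gt(area, 0)  # CCW orientation

  # a layer above the part is empty
  expect_length(layer_contour(m, 10), 0)
})

test_that("projection samples the layer surface and flags outside waypoints", {
  hf <- heightfield_from_function(function(x, y) 0 * x, c(0, 10), c(0, 10), 1)
  l <- conformal_layers(hf, data.frame(role = "infill", thickness = 1.2))[[1]]
  p <- project_to_surface(cbind(c(1, 5, 9), c(1, 5, 9)), l)
  expect_equal(p[, 3], rep(1.2, 3))

  # plane z = 2x: waypoint (0.5, y) projects to z = 1 + offset
  hf2 <- heightfield_from_function(function(x, y) 2 * x, c(0, 10), c(0, 10), 0.5)
  l2 <- conformal_layers(hf2, data.frame(role = "infill", thickness = 0.42))[[1]]
  expect_equal(project_to_surface(cbind(0.5, 3), l2)[, 3], 1.42,
               ignore_attr = TRUE)

  expect_error(project_to_surface(cbind(c(1, 50), c(1, 1)), l2),
               "waypoint 2")

  # saddle layer matches the analytic surface within the interpolation bound
  g <- expand.grid(x = seq(-10, 10, 1), y = seq(-10, 10, 1))
  hf3 <- heightfield_from_points(cbind(g$x, g$y, 0.01 * (g$x^2 - g$y^2)), 0.5)
  l3 <- conformal_layers(hf3, data.frame(role = "infill", thickness = 0.42))[[1]]
  px <- seq(-8, 8, length.out = 30); py <- seq(-8, 8, length.out = 30)
  p3 <- project_to_surface(cbind(px, py), l3)
  expect_lt(max(abs(p3[, 3] - (0.01 * (px^2 - py^2) + 0.42))), 0.02 / 8 + 1e-9)
})

test_that("path gradients recover analytic inclinations", {
  # horizontal path
  p <- cbind(seq(0, 10, 1), 0, 1)
  g <- path_gradient(p)
  expect_equal(g$alpha, rep(0, 11))

  # 45-degree ramp, ascending
  p2 <- cbind(seq(0, 10, 1), 0, seq(0, 10, 1))
  g2 <- path_gradient(p2)
  expect_equal(g2$alpha, rep(45, 11))
  expect_true(all(g2$sense == "ascending"))

  # sinusoid: central differences within the finite-difference bound
  x <- seq(0, 10, by = 0.05)
  p3 <- cbind(x, 0, sin(x))
  g3 <- path_gradient(p3)
  interior <- 2:(length(x) - 1)
  ref <- atan(abs(cos(x))) * 180 / pi
  expect_lt(max(abs(g3$alpha[interior] - ref[interior])), 0.05)

  expect_error(path_gradient(rbind(c(0, 0, 0), c(0, 0, 1))), "duplicate")
  expect_error(path_gradient(p3[1, , drop = FALSE]), "at least 2")
})

test_that("nozzle-height compensation follows the inclination law", {
  # flat substrate: both senses give h0
  expect_equal(adjust_nozzle_height(0.42, 0.84, 0, "ascending"), 0.42)
  expect_equal(adjust_nozzle_height(0.42, 0.84, 0, "descending"), 0.42)

  # hand-computed 45-degree case
  expect_equal(adjust_nozzle_height(0.42, 0.84, 45, "descending"),
               0.42 / cos(pi / 4) + 0.42 * tan(pi / 4), tolerance = 1e-12)
  expect_equal(adjust_nozzle_height(0.42, 0.84, 45, "descending"),
               1.01396969619670, tolerance = 1e-10)
  expect_equal(adjust_nozzle_height(0.42, 0.84, 45, "ascending"),
               0.17396969619670, tolerance = 1e-10)

  # branches symmetric about h0 / cos(alpha); divergence grows with alpha
  al <- seq(0, 80, by = 5)
  up <- adjust_nozzle_height(0.42, 0.84, al, rep("ascending", length(al)))
  dn <- adjust_nozzle_height(0.42, 0.84, al, rep("descending", length(al)))
  expect_equal((up + dn) / 2, 0.42 / cos(al * pi / 180))
  expect_true(all(diff(dn - up) >= 0))  # the branch gap widens with alpha
  expect_true(all(diff(abs(dn - 0.42)) >= 0))  # both diverge from h0
  expect_true(all(diff(abs(up - 0.42)) >= 0))

  # convention switch flips the branches
  expect_equal(adjust_nozzle_height(0.42, 0.84, 30, "ascending",
                                    sign_convention = "ascending_plus"),
               adjust_nozzle_height(0.42, 0.84, 30, "descending"))
  expect_error(adjust_nozzle_height(0.42, 0.84, 95, "ascending"), "90")
})

test_that("flow is slaved to speed and filament cross-section", {
  expect_equal(flow_rate(16.667, 0.84, 0.42), 5.8801176)
  expect_equal(flow_rate(16.667, 0.84, 0.84), 2 * 5.8801176)
  expect_equal(flow_rate(0, 0.84, 0.42), 0)
})
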