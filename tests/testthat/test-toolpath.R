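# Orientation fields, unit line families, grid graphs, contour trimming.

test_that("orientation field generators honour their modes and seeds", {
  f <- langer_field(3, 3, "constant", angle = 0)
  expect_equal(f$angles, matrix(0, 3, 3))

  r1 <- langer_field(5, 4, "random", seed = 9)
  r2 <- langer_field(5, 4, "random", seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$angles >= 0 & r1$angles < 180))

  ls <- langer_field(8, 2, "langer_sine", unit_size = 10, angle = 45,
                     amplitude = 20, period = 40)
  xc <- (1:8 - 0.5) * 10
  expect_equal(ls$angles[1, ], (45 + 20 * sin(2 * pi * xc / 40)) %% 180)
  expect_equal(ls$angles[1, ], ls$angles[2, ])

  # angles reduce modulo 180
  f2 <- orientation_field(matrix(c(190, -10), 1), 10)
  expect_equal(as.numeric(f2$angles), c(10, 170))
})

test_that("orientation fields round-trip through CSV", {
  f <- langer_field(4, 3, "random", seed = 2, unit_size = 7.5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_orientation_field(f, p)
  f2 <- read_orientation_field(p)
  expect_equal(f2$angles, f$angles, tolerance = 1e-6)
  expect_equal(f2$unit_size, 7.5)
})

test_that("unit line families have the constructed counts and symmetry", {
  segs <- generate_unit_lines(c(0, 0, 10, 10), 0, 1.14)
  expect_length(segs, 9)  # floor(5 / 1.14) = 4 on each side of the centre
  # all horizontal, spaced by 1.14, one through the centre
  ys <- sort(vapply(segs, function(s) s[1, 2], numeric(1)))
  expect_equal(diff(ys), rep(1.14, 8))
  expect_true(any(abs(ys - 5) < 1e-9))

  # 90-degree rotation maps the family onto the vertical one
  segs90 <- generate_unit_lines(c(0, 0, 10, 10), 90, 1.14)
  xs <- sort(vapply(segs90, function(s) s[1, 1], numeric(1)))
  expect_equal(xs, ys)

  # spacing beyond the unit support leaves the single centre line
  expect_length(generate_unit_lines(c(0, 0, 10, 10), 37, 20), 1)
})

test_that("matched line counts merge continuously across a border", {
  f <- langer_field(2, 1, "constant", angle = 0, unit_size = 10)
  g <- generate_grid_lines(f, spacing = 5, waypoints_per_unit = 10)
  expect_equal(length(g$x), 20)
  # every line continues across the border: for each right-border endpoint
  # of unit 1 there is a cross edge to unit 2
  cross <- g$unit[g$edges[, 1]] != g$unit[g$edges[, 2]]
  expect_equal(sum(cross), 3)  # three lines at spacing 5 on a 10 mm unit
})

test_that("orthogonal neighbours connect only at snapped junctions", {
  f <- orientation_field(matrix(c(0, 90), 1, 2), unit_size = 10)
  g <- generate_grid_lines(f, spacing = 5, waypoints_per_unit = 10)
  cross <- which(g$unit[g$edges[, 1]] != g$unit[g$edges[, 2]])
  # brute-force matching: endpoints on the shared border within tol
  ids1 <- which(g$unit == 1 & abs(g$x - 10) <= 1e-6)
  ids2 <- which(g$unit == 2 & abs(g$x - 10) <= 1e-6)
  for (e in cross) {
    a <- g$edges[e, 1]; b <- g$edges[e, 2]
    expect_true((a %in% ids1 && b %in% ids2) || (a %in% ids2 && b %in% ids1))
    expect_lte(sqrt((g$x[a] - g$x[b])^2 + (g$y[a] - g$y[b])^2), 2.5)
  }
})

test_that("the 8x8 benchmark discretization has exactly 640 nodes", {
  f <- langer_field(8, 8, "random", seed = 1, unit_size = 10)
  g <- generate_grid_lines(f, spacing = 10, waypoints_per_unit = 10)
  expect_equal(length(g$x), 640)
  expect_equal(length(unique(g$unit)), 64)
  expect_equal(as.numeric(table(g$unit)), rep(10, 64))
  # determinism
  g2 <- generate_grid_lines(langer_field(8, 8, "random", seed = 1, unit_size = 10),
                            spacing = 10, waypoints_per_unit = 10)
  expect_identical(g, g2)
})

test_that("trimming keeps exactly the in-polygon nodes and clips crossing edges", {
  f <- langer_field(3, 3, "constant", angle = 15, unit_size = 10)
  g <- generate_grid_lines(f, spacing = 4, waypoint_spacing = 2)

  # contour containing everything: unchanged
  big <- rbind(c(-5, -5), c(35, -5), c(35, 35), c(-5, 35))
  expect_identical(trim_to_contour(g, big), g)

  # containing nothing: empty graph
  none <- rbind(c(100, 100), c(101, 100), c(101, 101), c(100, 101))
  expect_length(trim_to_contour(g, none)$x, 0)

  # square window: surviving original nodes equal the brute-force count
  win <- rbind(c(5, 5), c(25, 5), c(25, 25), c(5, 25))
  tg <- trim_to_contour(g, win)
  inside_ref <- winding_inside(g$x, g$y, win) |
    (pmin(abs(g$x - 5), abs(g$x - 25)) < 1e-9 & g$y >= 5 - 1e-9 & g$y <= 25 + 1e-9) |
    (pmin(abs(g$y - 5), abs(g$y - 25)) < 1e-9 & g$x >= 5 - 1e-9 & g$x <= 25 + 1e-9)
  n_boundary_inserted <- length(tg$x) - sum(inside_ref)
  expect_gte(n_boundary_inserted, 0)
  # every surviving node is inside or on the window
  expect_true(all(tg$x >= 5 - 1e-6 & tg$x <= 25 + 1e-6))
  expect_true(all(tg$y >= 5 - 1e-6 & tg$y <= 25 + 1e-6))
  # inserted boundary nodes sit exactly on the window border
  extra <- tail(seq_along(tg$x), n_boundary_inserted)
  if (length(extra))
    expect_true(all(abs(pmin(abs(tg$x[extra] - 5), abs(tg$x[extra] - 25))) < 1e-6 |
                      abs(pmin(abs(tg$y[extra] - 5), abs(tg$y[extra] - 25))) < 1e-6))
})
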