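# Program assembly, dialects, conservation, determinism.

simple_setup <- function() {
  list(field = langer_field(3, 3, "constant", unit_size = 10),
       voxel = voxel_spec(0.84, 0.84, 0.84, 0.42, 1.14, 1.14, 100, 100),
       plan = data.frame(role = "infill", thickness = 0.42),
       options = list(restarts = 10, waypoint_spacing = 2.5, seed = 1))
}

test_that("a flat single-layer program reproduces the optimizer's paths", {
  s <- simple_setup()
  pr <- plan_print(s$field, s$voxel, s$plan, options = s$options)
  cm <- pr$commands
  expect_true(all(cm$feed == 16.667))
  expect_true(all(cm$flow[!cm$extrude] == 0))

  # rebuild the optimizer's path set the way plan_print does
  g <- generate_grid_lines(s$field, spacing = s$voxel$L2,
                           waypoint_spacing = 2.5)
  ps <- optimize_paths(g, restarts = 10, seed = 1 + 1)  # seed + layer index
  collapse <- function(p) {
    dup <- c(FALSE, abs(diff(g$x[p])) < 1e-9 & abs(diff(g$y[p])) < 1e-9)
    p[!dup]
  }
  ref <- do.call(rbind, lapply(ps$paths, function(p)
    cbind(g$x[collapse(p)], g$y[collapse(p)])))
  expect_equal(unname(cbind(cm$x, cm$y)), unname(ref))
  # travel moves mark path starts
  expect_equal(sum(!cm$extrude), ps$n_paths)
})

test_that("commanded extrusion volume matches filament geometry on a flat part", {
  s <- simple_setup()
  pr <- plan_print(s$field, s$voxel, s$plan, options = s$options)
  cm <- pr$commands
  seg <- sqrt(diff(cm$x)^2 + diff(cm$y)^2 + diff(cm$z)^2)
  i <- which(cm$extrude[-1]) + 1L
  line_len <- sum(seg[i - 1L])
  expect_equal(extruded_volume(pr), 0.84 * 0.42 * line_len, tolerance = 1e-9)
})

test_that("a conformal plan over a saddle puck stacks the planned layers", {
  pk <- make_paraboloid_puck(extent = 30, curvature = 0.01, thickness = 4,
                             resolution = 14)
  f <- langer_field(4, 4, "constant", unit_size = 10, origin = c(-20, -20))
  v <- voxel_spec(0.84, 0.84, 0.84, 0.42, 1.14, 1.14, 100, 100)
  plan <- data.frame(role = c("bottom_cover", "infill", "infill", "top_cover"),
                     thickness = c(0.6, 0.84, 0.42, 0.6))
  pr <- plan_print(f, v, plan, mesh = pk,
                   options = list(restarts = 5, waypoint_spacing = 3,
                                  grid_spacing = 2, reorient = FALSE))
  cm <- pr$commands
  expect_equal(sort(unique(cm$layer)), 1:4)
  expect_equal(unique(cm$role[cm$layer == 1]), "bottom_cover")
  expect_equal(unique(cm$role[cm$layer == 2]), "infill")
  expect_equal(unique(cm$role[cm$layer == 4]), "top_cover")
  # z rises with the layer stack
  expect_gt(min(cm$z[cm$layer == 4]), min(cm$z[cm$layer == 1]))
})

test_that("successive infill layers alternate orthogonally", {
  f <- langer_field(2, 2, "constant", angle = 0, unit_size = 10)
  v <- voxel_spec(0.84, 0.84, 0.42, 0.42, 1.14, 1.14, 100, 100)
  plan <- data.frame(role = c("infill", "infill"), thickness = c(0.42, 0.42))
  pr <- plan_print(f, v, plan, options = list(restarts = 5, waypoint_spacing = 2.5))
  cm <- pr$commands
  dir_of <- function(layer) {
    d <- cm[cm$layer == layer & cm$extrude, ]
    seg <- cbind(diff(d$x), diff(d$y))
    seg <- seg[rowSums(abs(seg)) > 1e-9, , drop = FALSE]
    mean(abs(seg[, 1]) > abs(seg[, 2]))
  }
  # layer 1 mostly along x (angle 0), layer 2 mostly along y
  expect_gt(dir_of(1), 0.6)
  expect_lt(dir_of(2), 0.4)
})

test_that("programs round-trip through both dialects at 6 decimals", {
  s <- simple_setup()
  pr <- plan_print(s$field, s$voxel, s$plan, options = s$options)
  r6 <- function(v) round(v, 6)

  p1 <- withr::local_tempfile(fileext = ".gcode")
  write_gcode(pr, p1)
  rt <- read_machine_program(p1)
  for (col in c("x", "y", "z", "feed", "flow"))
    expect_equal(rt$commands[[col]], r6(pr$commands[[col]]))
  expect_equal(rt$commands$extrude, pr$commands$extrude)

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_gcode(pr, p2, dialect = "command_csv")
  rt2 <- read_machine_program(p2, dialect = "command_csv")
  for (col in c("x", "y", "z", "feed", "flow"))
    expect_equal(rt2$commands[[col]], r6(pr$commands[[col]]))
  expect_equal(rt2$commands$role, pr$commands$role)

  # E is cumulative, hence non-decreasing
  gl <- grep("^G1", readLines(p1), value = TRUE)
  E <- as.numeric(sub(".*E([0-9.]+).*", "\\1", gl))
  expect_true(all(diff(E) >= 0))
})

test_that("an empty program writes a header-only file", {
  empty <- machine_program(data.frame(x = numeric(0), y = numeric(0),
                                      z = numeric(0), feed = numeric(0),
                                      flow = numeric(0), extrude = logical(0),
                                      layer = integer(0), role = character(0),
                                      ink = character(0)),
                           meta = list(units = "mm", nozzle_d = 0.84,
                                       speed = 16.667))
  p <- withr::local_tempfile(fileext = ".gcode")
  write_gcode(empty, p)
  lines <- readLines(p)
  expect_length(lines, 1)
  expect_match(lines, "^;")
  expect_equal(nrow(read_machine_program(p)$commands), 0)
})

test_that("replanning with identical configuration is byte-identical", {
  s <- simple_setup()
  pr1 <- plan_print(s$field, s$voxel, s$plan, options = s$options)
  pr2 <- plan_print(s$field, s$voxel, s$plan, options = s$options)
  expect_identical(pr1, pr2)
  f1 <- withr::local_tempfile(fileext = ".gcode")
  f2 <- withr::local_tempfile(fileext = ".gcode")
  write_gcode(pr1, f1); write_gcode(pr2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("program validation enforces the command invariants", {
  bad <- data.frame(x = 1, y = 1, z = 1, feed = 1, flow = 2, extrude = FALSE,
                    layer = 1L, role = "infill", ink = "silicone")
  expect_error(machine_program(bad), "flow must be 0")
  bad2 <- transform(bad, flow = 0, feed = 0)
  expect_error(machine_program(bad2), "feed")
  bad3 <- transform(bad, flow = 0, x = NA)
  expect_error(machine_program(bad3), "finite")
})
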