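# Scattered-point interpolation onto a regular grid, and conformal layers.

# Bowyer-Watson Delaunay triangulation of 2-D points.
# Returns an m x 3 matrix of 1-based indices into (x, y).
delaunay_xy <- function(x, y) {
  n <- length(x)
  ap_check(n >= 3, "delaunay: at least 3 points required")
  # super-triangle comfortably enclosing all points
  cx <- mean(range(x)); cy <- mean(range(y))
  span <- max(diff(range(x)), diff(range(y)), 1e-9) * 20
  px <- c(x, cx - span, cx + span, cx)
  py <- c(y, cy - span, cy - span, cy + span)
  sup <- n + 1:3

  cap <- 4L * n + 16L
  tri <- matrix(0L, cap, 3)
  ccx <- numeric(cap); ccy <- numeric(cap); cr2 <- numeric(cap)
  active <- logical(cap)
  ntri <- 0L

  circum <- function(i, j, k) {
    ax <- px[i]; ay <- py[i]; bx <- px[j]; by <- py[j]; qx <- px[k]; qy <- py[k]
    d <- 2 * (ax * (by - qy) + bx * (qy - ay) + qx * (ay - by))
    if (abs(d) < 1e-14) return(c(NA, NA, NA))
    ux <- ((ax^2 + ay^2) * (by - qy) + (bx^2 + by^2) * (qy - ay) +
             (qx^2 + qy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (qx - bx) + (bx^2 + by^2) * (ax - qx) +
             (qx^2 + qy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  add_tri <- function(i, j, k) {
    cc <- circum(i, j, k)
    if (is.na(cc[1])) return(invisible(NULL))  # degenerate sliver, skip
    ntri <<- ntri + 1L
    if (ntri > length(active)) {  # grow storage
      grow <- length(active)
      tri <<- rbind(tri, matrix(0L, grow, 3))
      ccx <<- c(ccx, numeric(grow)); ccy <<- c(ccy, numeric(grow))
      cr2 <<- c(cr2, numeric(grow)); active <<- c(active, logical(grow))
    }
    tri[ntri, ] <<- c(i, j, k)
    ccx[ntri] <<- cc[1]; ccy[ntri] <<- cc[2]; cr2[ntri] <<- cc[3]
    active[ntri] <<- TRUE
    invisible(NULL)
  }
  add_tri(sup[1], sup[2], sup[3])

  for (p in seq_len(n)) {
    idx <- which(active[seq_len(ntri)])
    bad <- idx[(px[p] - ccx[idx])^2 + (py[p] - ccy[idx])^2 <= cr2[idx] * (1 + 1e-12)]
    if (length(bad) == 0L) next  # duplicate point already covered
    # boundary of the cavity: edges used by exactly one bad triangle
    e <- rbind(tri[bad, c(1, 2), drop = FALSE], tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- ekey %in% names(which(table(ekey) == 1L))
    active[bad] <- FALSE
    for (r in which(once)) add_tri(e[r, 1], e[r, 2], p)
  }
  keep <- which(active[seq_len(ntri)])
  out <- tri[keep, , drop = FALSE]
  out <- out[rowSums(matrix(out %in% sup, ncol = 3)) == 0L, , drop = FALSE]
  ap_check(nrow(out) > 0, "delaunay: degenerate (collinear) input")
  out
}

#' Interpolate scattered points onto a regular height-field grid
#'
#' Triangulates the scattered (x, y) points (Delaunay) and linearly
#' (barycentrically) interpolates z onto a regular grid of the given
#' spacing covering the points' bounding box.  Grid cells outside the
#' convex hull of the input are `NA` and are excluded from layer
#' generation and projection.
#'
#' @param points matrix or data frame with columns x, y, z (mm).
#' @param spacing grid spacing, mm (> 0).
#' @return An object of class `height_field`: list with `z` (matrix,
#'   rows = y index, cols = x index), `x`, `y` (grid coordinates),
#'   `spacing`, `origin`.
#' @export
heightfield_from_points <- function(points, spacing) {
  points <- as.matrix(points)
  ap_check(ncol(points) >= 3, "heightfield_from_points: `points` needs columns x, y, z")
  ap_check(is.numeric(spacing) && length(spacing) == 1L && spacing > 0,
           "heightfield_from_points: `spacing` must be > 0")
  ap_check(nrow(points) >= 3, "heightfield_from_points: at least 3 points required")
  pts <- points[!duplicated(round(points[, 1:2] / 1e-9)), , drop = FALSE]
  tris <- delaunay_xy(pts[, 1], pts[, 2])  # errors on collinear input
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  gx <- seq(xr[1], xr[2], by = spacing)
  if (tail(gx, 1) < xr[2] - 1e-9) gx <- c(gx, xr[2])
  gy <- seq(yr[1], yr[2], by = spacing)
  if (tail(gy, 1) < yr[2] - 1e-9) gy <- c(gy, yr[2])
  z <- matrix(NA_real_, length(gy), length(gx))
  GX <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  GY <- matrix(gy, length(gy), length(gx))
  done <- matrix(FALSE, length(gy), length(gx))
  tol <- 1e-9
  for (t in seq_len(nrow(tris))) {
    a <- pts[tris[t, 1], ]; b <- pts[tris[t, 2], ]; cc <- pts[tris[t, 3], ]
    cand <- which(!done &
                    GX >= min(a[1], b[1], cc[1]) - tol &
                    GX <= max(a[1], b[1], cc[1]) + tol &
                    GY >= min(a[2], b[2], cc[2]) - tol &
                    GY <= max(a[2], b[2], cc[2]) + tol)
    if (length(cand) == 0L) next
    det <- (b[2] - cc[2]) * (a[1] - cc[1]) + (cc[1] - b[1]) * (a[2] - cc[2])
    if (abs(det) < 1e-14) next
    l1 <- ((b[2] - cc[2]) * (GX[cand] - cc[1]) + (cc[1] - b[1]) * (GY[cand] - cc[2])) / det
    l2 <- ((cc[2] - a[2]) * (GX[cand] - cc[1]) + (a[1] - cc[1]) * (GY[cand] - cc[2])) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    hit <- cand[inside]
    z[hit] <- l1[inside] * a[3] + l2[inside] * b[3] + l3[inside] * cc[3]
    done[hit] <- TRUE
  }
  structure(list(z = z, x = gx, y = gy, spacing = spacing,
                 origin = c(xr[1], yr[1])),
            class = "height_field")
}

#' Build a height field directly from a z function on a grid
#'
#' Convenience constructor for analytically defined substrates.
#'
#' @param f function of (x, y) returning z (mm), vectorized.
#' @param xlim,ylim extents, mm.
#' @param spacing grid spacing, mm.
#' @return A `height_field`.
#' @export
heightfield_from_function <- function(f, xlim, ylim, spacing) {
  gx <- seq(xlim[1], xlim[2], by = spacing)
  gy <- seq(ylim[1], ylim[2], by = spacing)
  z <- outer(gy, gx, function(Y, X) f(X, Y))
  structure(list(z = z, x = gx, y = gy, spacing = spacing,
                 origin = c(xlim[1], ylim[1])),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf("Height field: %d x %d grid, spacing %g mm, z in [%.3g, %.3g] mm (%d NA cells)\n",
              length(x$x), length(x$y), x$spacing,
              suppressWarnings(min(x$z, na.rm = TRUE)),
              suppressWarnings(max(x$z, na.rm = TRUE)), sum(is.na(x$z))))
  invisible(x)
}

# bilinear sample of a height field at points (px, py); NA outside the
# defined region
sample_heightfield <- function(hf, px, py) {
  nx <- length(hf$x); ny <- length(hf$y)
  fx <- (px - hf$x[1]) / diff(range(hf$x)) * (nx - 1) + 1
  fy <- (py - hf$y[1]) / diff(range(hf$y)) * (ny - 1) + 1
  # grids built with by=spacing are uniform except possibly the last step;
  # use interval lookup to stay exact
  fx <- approx_index(hf$x, px)
  fy <- approx_index(hf$y, py)
  i0 <- floor(fy); j0 <- floor(fx)
  out <- rep(NA_real_, length(px))
  okk <- !is.na(fx) & !is.na(fy)
  i0 <- pmin(pmax(i0, 1L), ny - 1L); j0 <- pmin(pmax(j0, 1L), nx - 1L)
  ty <- fy - i0; tx <- fx - j0
  z00 <- hf$z[cbind(i0, j0)]; z01 <- hf$z[cbind(i0, j0 + 1L)]
  z10 <- hf$z[cbind(i0 + 1L, j0)]; z11 <- hf$z[cbind(i0 + 1L, j0 + 1L)]
  val <- (1 - ty) * ((1 - tx) * z00 + tx * z01) + ty * ((1 - tx) * z10 + tx * z11)
  out[okk] <- val[okk]
  out
}

# fractional index of v within the (sorted, near-uniform) grid g; NA outside
approx_index <- function(g, v) {
  n <- length(g)
  idx <- findInterval(v, g, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(v))
  ok <- v >= g[1] - 1e-9 & v <= g[n] + 1e-9
  idx <- pmin(pmax(idx, 1L), n - 1L)
  out[ok] <- idx[ok] + (v[ok] - g[idx[ok]]) / (g[idx[ok] + 1L] - g[idx[ok]])
  out
}

#' Conformal layer stack over a bottom template
#'
#' Each layer surface is the bottom height field translated vertically by
#' the cumulative thickness of the layers below it plus its own
#' thickness; this matches a 3-axis gantry that offsets along Z rather
#' than along surface normals (the residual inclination error is
#' compensated downstream by [adjust_nozzle_height()]).
#'
#' @param base a `height_field`, the nonplanar bottom template.
#' @param plan data frame with columns `role` (one of `"bottom_cover"`,
#'   `"infill"`, `"top_cover"`, `"sacrificial"`) and `thickness` (mm > 0),
#'   ordered bottom to top.
#' @return List of `layer_surface` objects (fields `index`, `base`,
#'   `offset`, `thickness`, `role`).
#' @export
conformal_layers <- function(base, plan) {
  ap_check(inherits(base, "height_field"), "conformal_layers: `base` must be a height_field")
  ap_check(is.data.frame(plan) && all(c("role", "thickness") %in% names(plan)),
           "conformal_layers: `plan` needs columns `role` and `thickness`")
  ap_check(nrow(plan) > 0, "conformal_layers: empty plan")
  ap_check(all(plan$thickness > 0), "conformal_layers: thicknesses must be > 0")
  roles <- c("bottom_cover", "infill", "top_cover", "sacrificial")
  ap_check(all(plan$role %in% roles),
           paste0("conformal_layers: role must be one of ", paste(roles, collapse = ", ")))
  offs <- cumsum(plan$thickness)
  lapply(seq_len(nrow(plan)), function(k)
    structure(list(index = k, base = base, offset = offs[k],
                   thickness = plan$thickness[k],
                   role = plan$role[k]),
              class = "layer_surface"))
}

#' @export
print.layer_surface <- function(x, ...) {
  cat(sprintf("Layer %d (%s): offset %+.3g mm, thickness %g mm\n",
              x$index, x$role, x$offset, x$thickness))
  invisible(x)
}

# z of the layer surface at (px, py)
layer_z <- function(layer, px, py) {
  sample_heightfield(layer$base, px, py) + layer$offset
}

#' Project a 2-D toolpath onto a conformal layer surface
#'
#' @param path2d n x 2 matrix of XY waypoints (mm).
#' @param layer a `layer_surface` from [conformal_layers()].
#' @return n x 3 matrix of 3-D waypoints; XY unchanged, z sampled
#'   bilinearly from the layer surface.
#' @export
project_to_surface <- function(path2d, layer) {
  ap_check(inherits(layer, "layer_surface"), "project_to_surface: `layer` must be a layer_surface")
  path2d <- as.matrix(path2d)
  ap_check(ncol(path2d) == 2, "project_to_surface: `path2d` must be n x 2")
  z <- layer_z(layer, path2d[, 1], path2d[, 2])
  if (anyNA(z)) {
    stop(sprintf("project_to_surface: waypoint %d (%.4g, %.4g) lies outside the layer's defined region",
                 which(is.na(z))[1], path2d[which(is.na(z))[1], 1],
                 path2d[which(is.na(z))[1], 2]), call. = FALSE)
  }
  cbind(x = path2d[, 1], y = path2d[, 2], z = z)
}
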