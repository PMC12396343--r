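#' Reorient a mesh to minimize its overall height
#'
#' Finds tilt angles about the X and Y axes that minimize the Z-extent of
#' the mesh.  The search is deterministic: a principal-axis candidate (the
#' least-variance axis of the vertex cloud rotated onto Z) is accepted
#' only if it strictly lowers the extent, then an exhaustive 1-degree grid
#' over both tilt angles in +/-45 degrees refines it.  Ties prefer the
#' smallest total tilt, so an already-minimal mesh is returned unchanged.
#'
#' @param mesh a [tri_mesh()].
#' @return List with `mesh` (reoriented), `rotation` (3 x 3 matrix),
#'   `tilt_x`, `tilt_y` (degrees, of the grid stage), `z_extent` (mm).
#' @export
reorient_min_height <- function(mesh) {
  ap_check(inherits(mesh, "tri_mesh"), "reorient_min_height: `mesh` must be a tri_mesh")
  v <- mesh$vertices
  ap_check(nrow(v) >= 3, "reorient_min_height: degenerate mesh")
  zext <- function(V) diff(range(V[, 3]))

  base_R <- diag(3)
  ext0 <- zext(v)
  # principal-axis initialization: rotate least-variance axis onto Z
  cv <- stats::cov(v)
  ev <- eigen(cv, symmetric = TRUE)
  axes <- ev$vectors  # columns ordered by decreasing variance
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  Rpca <- t(axes[, c(1, 2, 3)])  # maps principal axes to x, y, z
  vp <- v %*% t(Rpca)
  if (zext(vp) < ext0 - 1e-9) {
    base_R <- Rpca
    v_base <- vp
  } else {
    v_base <- v
  }

  angles <- -45:45
  best <- c(ext = zext(v_base), ax = 0, ay = 0)
  # z' = -cos(ax) sin(ay) x + sin(ax) y + cos(ax) cos(ay) z  for Rx(ax) Ry(ay)
  grid <- expand.grid(ax = angles, ay = angles)
  ca <- cos(grid$ax * pi / 180); sa <- sin(grid$ax * pi / 180)
  cb <- cos(grid$ay * pi / 180); sb <- sin(grid$ay * pi / 180)
  K <- rbind(-ca * sb, sa, ca * cb)  # 3 x P
  block <- 1500L
  ext <- numeric(nrow(grid))
  for (st in seq(1, nrow(grid), by = block)) {
    en <- min(st + block - 1L, nrow(grid))
    Z <- v_base %*% K[, st:en, drop = FALSE]
    ext[st:en] <- apply(Z, 2, function(col) diff(range(col)))
  }
  tot_tilt <- abs(grid$ax) + abs(grid$ay)
  ord <- order(ext, tot_tilt, seq_along(ext))
  pick <- ord[1]
  if (ext[pick] < best["ext"] - 1e-9) {
    best <- c(ext = ext[pick], ax = grid$ax[pick], ay = grid$ay[pick])
  }
  Rg <- rot_x(best["ax"]) %*% rot_y(best["ay"])
  Rtot <- Rg %*% base_R
  out <- mesh
  out$vertices <- mesh$vertices %*% t(Rtot)
  out$normals <- mesh$normals %*% t(Rtot)
  list(mesh = out, rotation = Rtot, tilt_x = unname(best["ax"]),
       tilt_y = unname(best["ay"]), z_extent = unname(best["ext"]))
}

#' Split a mesh into bottom and top surfaces by normal direction
#'
#' A vertex belongs to the bottom set iff the Z-component of its unit
#' normal is below `nz_threshold`; vertices with |nz| < 1e-6 (vertical
#' walls) are assigned to the top set and counted in a warning.  Faces
#' are assigned by majority vote of their vertices.
#'
#' @param mesh a [tri_mesh()].
#' @param nz_threshold threshold on the normal Z-component (default 0).
#' @return List with elements `bottom` and `top`, each a list of
#'   `vertex_idx` and `face_idx`, plus `n_wall` (count of near-vertical
#'   normals).
#' @export
split_top_bottom <- function(mesh, nz_threshold = 0) {
  ap_check(inherits(mesh, "tri_mesh"), "split_top_bottom: `mesh` must be a tri_mesh")
  nz <- mesh$normals[, 3]
  wall <- abs(nz) < 1e-6
  is_bottom <- nz < nz_threshold & !wall
  if (any(wall))
    warning(sprintf("split_top_bottom: %d vertices have near-vertical normals; assigned to top",
                    sum(wall)), call. = FALSE)
  votes <- matrix(is_bottom[mesh$faces], ncol = 3)
  face_bottom <- rowSums(votes) >= 2
  list(bottom = list(vertex_idx = which(is_bottom),
                     face_idx = which(face_bottom)),
       top = list(vertex_idx = which(!is_bottom),
                  face_idx = which(!face_bottom)),
       n_wall = sum(wall))
}

#' Contour of a conformal layer through a mesh
#'
#' Computes the closed XY polygon(s) where the mesh surface crosses the
#' layer surface (base template plus vertical offset), i.e. the footprint
#' boundary of the layer inside the solid.  Faces are iso-contoured on
#' the signed vertical distance between mesh vertices and the layer
#' surface, crossing segments are chained, and each closed chain is
#' returned counterclockwise.
#'
#' @param mesh a [tri_mesh()].
#' @param layer a `layer_surface`, or a single number interpreted as a
#'   horizontal plane z = layer (mm).
#' @return List of polygons (n x 2 matrices, CCW, not closed); empty list
#'   when the layer does not intersect the mesh.
#' @export
layer_contour <- function(mesh, layer) {
  ap_check(inherits(mesh, "tri_mesh"), "layer_contour: `mesh` must be a tri_mesh")
  v <- mesh$vertices
  if (is.numeric(layer) && length(layer) == 1L) {
    dvert <- v[, 3] - layer
  } else {
    ap_check(inherits(layer, "layer_surface"),
             "layer_contour: `layer` must be a layer_surface or a z value")
    zs <- layer_z(layer, v[, 1], v[, 2])
    # vertices outside the template's defined region: clamp to nearest cell
    if (anyNA(zs)) {
      hf <- layer$base
      pxc <- pmin(pmax(v[, 1], min(hf$x)), max(hf$x))
      pyc <- pmin(pmax(v[, 2], min(hf$y)), max(hf$y))
      zs2 <- sample_heightfield(hf, pxc, pyc) + layer$offset
      zs[is.na(zs)] <- zs2[is.na(zs)]
    }
    dvert <- v[, 3] - zs
  }
  dvert[abs(dvert) < 1e-12] <- 1e-12  # nudge exact hits off the surface
  f <- mesh$faces
  segs <- list()
  for (i in seq_len(nrow(f))) {
    d <- dvert[f[i, ]]
    if (all(d > 0) || all(d < 0)) next
    pts <- matrix(0, 0, 2)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      if (d[e[1]] * d[e[2]] < 0) {
        t <- d[e[1]] / (d[e[1]] - d[e[2]])
        p <- v[f[i, e[1]], 1:2] + t * (v[f[i, e[2]], 1:2] - v[f[i, e[1]], 1:2])
        pts <- rbind(pts, p)
      }
    }
    if (nrow(pts) == 2) segs[[length(segs) + 1L]] <- pts
  }
  if (length(segs) == 0L) return(list())
  chain_segments(segs)
}

# chain unordered segments into closed CCW polygons
chain_segments <- function(segs, tol = 1e-7) {
  key <- function(p) paste(round(p[1] / tol), round(p[2] / tol))
  ends <- lapply(segs, function(s) c(key(s[1, ]), key(s[2, ])))
  lookup <- new.env(parent = emptyenv())
  for (i in seq_along(segs)) for (k in 1:2) {
    kk <- ends[[i]][k]
    lookup[[kk]] <- c(if (!is.null(lookup[[kk]])) lookup[[kk]], i)
  }
  used <- logical(length(segs))
  polys <- list()
  for (start in seq_along(segs)) {
    if (used[start]) next
    used[start] <- TRUE
    poly <- segs[[start]]
    repeat {
      tailk <- key(poly[nrow(poly), ])
      nxt <- setdiff(lookup[[tailk]], which(used))
      if (length(nxt) == 0L) break
      i <- nxt[1]
      used[i] <- TRUE
      s <- segs[[i]]
      if (key(s[1, ]) == tailk) poly <- rbind(poly, s[2, ])
      else poly <- rbind(poly, s[1, ])
    }
    closed <- sqrt(sum((poly[1, ] - poly[nrow(poly), ])^2)) <= 10 * tol
    if (closed && nrow(poly) > 3) {
      poly <- poly[-nrow(poly), , drop = FALSE]
      # drop duplicate consecutive points
      d <- sqrt(rowSums((poly - poly[c(2:nrow(poly), 1), ])^2))
      poly <- poly[d > tol, , drop = FALSE]
      if (nrow(poly) >= 3) polys[[length(polys) + 1L]] <- orient_ccw(poly)
    } else if (!closed && nrow(poly) >= 3) {
      warning("layer_contour: open contour chain dropped", call. = FALSE)
    }
  }
  polys
}

#' Per-waypoint inclination along a 3-D path
#'
#' Computes the local substrate inclination experienced while travelling
#' a 3-D path: alpha = atan(|dz/ds|) where s is the horizontal (XY)
#' arclength, using central differences in the interior and one-sided
#' differences at the ends.  The travel sense is ascending where z
#' increases along the travel direction.
#'
#' @param path3d n x 3 matrix of waypoints (mm), n >= 2.
#' @return Data frame with columns `alpha` (degrees, >= 0) and `sense`
#'   (`"ascending"` / `"descending"`).
#' @export
path_gradient <- function(path3d) {
  path3d <- as.matrix(path3d)
  ap_check(ncol(path3d) == 3, "path_gradient: `path3d` must be n x 3")
  n <- nrow(path3d)
  ap_check(n >= 2, "path_gradient: at least 2 waypoints required")
  step <- sqrt(rowSums((path3d[-1, 1:2, drop = FALSE] -
                          path3d[-n, 1:2, drop = FALSE])^2))
  ap_check(all(step > 1e-12),
           "path_gradient: duplicate consecutive waypoints")
  s <- c(0, cumsum(step))
  z <- path3d[, 3]
  dzds <- numeric(n)
  dzds[1] <- (z[2] - z[1]) / (s[2] - s[1])
  dzds[n] <- (z[n] - z[n - 1]) / (s[n] - s[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    dzds[i] <- (z[i + 1] - z[i - 1]) / (s[i + 1] - s[i - 1])
  }
  data.frame(alpha = atan(abs(dzds)) * 180 / pi,
             sense = ifelse(dzds > 0, "ascending", "descending"))
}

#' Inclination-compensated nozzle height
#'
#' On an inclined substrate the commanded print-line height must be
#' corrected for the local slope: \deqn{h = h_0/\cos\alpha \pm
#' (d/2)\tan\alpha,} with the plus branch when travelling downhill
#' (descending: the leading nozzle edge hangs over the lower side) and
#' the minus branch when ascending.  Both branches reduce to `h0` on a
#' horizontal substrate.  The sign convention can be flipped via
#' `sign_convention` should a printhead geometry require it.
#'
#' @param h0 desired layer height, mm.
#' @param d nozzle inner diameter, mm.
#' @param alpha local inclination, degrees, in [0, 90).
#' @param travel_sense `"ascending"` or `"descending"` (vectorized).
#' @param sign_convention `"descending_plus"` (default) or
#'   `"ascending_plus"`.
#' @return Adjusted height h, mm (> 0).
#' @examples
#' adjust_nozzle_height(0.42, 0.84, 45, "descending")  # 1.014
#' adjust_nozzle_height(0.42, 0.84, 45, "ascending")   # 0.174
#' @export
adjust_nozzle_height <- function(h0, d, alpha, travel_sense,
                                 sign_convention = c("descending_plus", "ascending_plus")) {
  sign_convention <- match.arg(sign_convention)
  ap_check(all(h0 > 0), "adjust_nozzle_height: `h0` must be > 0")
  ap_check(all(d > 0), "adjust_nozzle_height: `d` must be > 0")
  ap_check(all(alpha >= 0 & alpha < 90),
           "adjust_nozzle_height: `alpha` must lie in [0, 90) degrees")
  ap_check(all(travel_sense %in% c("ascending", "descending")),
           "adjust_nozzle_height: `travel_sense` must be ascending/descending")
  rad <- alpha * pi / 180
  plus_sense <- if (sign_convention == "descending_plus") "descending" else "ascending"
  sgn <- ifelse(travel_sense == plus_sense, 1, -1)
  h <- h0 / cos(rad) + sgn * (d / 2) * tan(rad)
  ap_check(all(h > 0),
           "adjust_nozzle_height: adjusted height is non-positive (alpha too steep for h0)")
  h
}

#' Volumetric flow for a rectangular filament
#'
#' The extrusion rate is slaved to the commanded speed so that the
#' deposited filament has width `d` and height `h`: Q = speed * d * h.
#'
#' @param speed travel speed, mm/s.
#' @param d nozzle inner diameter (= filament width), mm.
#' @param h print-line height, mm.
#' @return Volumetric flow, mm^3/s.
#' @export
flow_rate <- function(speed, d, h) {
  ap_check(all(speed >= 0), "flow_rate: `speed` must be >= 0")
  ap_check(all(d > 0) && all(h > 0), "flow_rate: `d` and `h` must be > 0")
  speed * d * h
}
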