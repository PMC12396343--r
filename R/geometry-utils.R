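# Small planar-geometry primitives shared by the slicing and toolpath code.

# even-odd ray-casting point-in-polygon; boundary points count as inside
# (within tol). px, py vectors; poly = closed or open n x 2 matrix (CCW or CW).
point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n >= 2 && all(abs(poly[1, ] - poly[n, ]) < tol)) poly <- poly[-n, , drop = FALSE]
  n <- nrow(poly)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary test: point within tol of segment i-j
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / L2)) else 0
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    on_edge <- on_edge | d2 <= tol^2
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside | on_edge
}

# signed polygon area (positive for CCW); poly open n x 2
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# ensure CCW orientation
orient_ccw <- function(poly) {
  if (polygon_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

# Liang-Barsky clip of segment (p0, p1) to axis-aligned rect [x0,x1]x[y0,y1].
# Returns NULL or 2 x 2 matrix of the clipped endpoints.
clip_segment_rect <- function(p0, p1, x0, x1, y0, y1) {
  d <- p1 - p0
  p <- c(-d[1], d[1], -d[2], d[2])
  q <- c(p0[1] - x0, x1 - p0[1], p0[2] - y0, y1 - p0[2])
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    if (abs(p[k]) < 1e-15) {
      if (q[k] < 0) return(NULL)
    } else {
      t <- q[k] / p[k]
      if (p[k] < 0) { if (t > t1) return(NULL); if (t > t0) t0 <- t }
      else { if (t < t0) return(NULL); if (t < t1) t1 <- t }
    }
  }
  rbind(p0 + t0 * d, p0 + t1 * d)
}

# intersection parameter of segment a0->a1 with polygon boundary; returns
# sorted vector of t in (0,1) where the segment crosses any polygon edge
segment_polygon_crossings <- function(a0, a1, poly, tol = 1e-12) {
  n <- nrow(poly)
  if (n >= 2 && all(abs(poly[1, ] - poly[n, ]) < 1e-12)) poly <- poly[-n, , drop = FALSE]
  n <- nrow(poly)
  r <- a1 - a0
  ts <- numeric(0)
  j <- n
  for (i in seq_len(n)) {
    b0 <- poly[j, ]; b1 <- poly[i, ]
    s <- b1 - b0
    den <- r[1] * s[2] - r[2] * s[1]
    if (abs(den) > tol) {
      qp <- b0 - a0
      t <- (qp[1] * s[2] - qp[2] * s[1]) / den
      u <- (qp[1] * r[2] - qp[2] * r[1]) / den
      if (t > tol && t < 1 - tol && u >= -tol && u <= 1 + tol)
        ts <- c(ts, t)
    }
    j <- i
  }
  sort(unique(ts))
}

# rotation matrices (degrees)
rot_x <- function(a) {
  r <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
}
rot_y <- function(a) {
  r <- a * pi / 180
  matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
}
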