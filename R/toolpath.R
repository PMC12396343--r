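#' Parallel print lines filling one grid unit
#'
#' Generates the family of parallel segments at orientation `phi`
#' (degrees) with perpendicular spacing `spacing`, clipped to the unit
#' rectangle.  The family is anchored so that one line passes through the
#' unit centre; if the spacing exceeds the unit's support only that
#' centre line is returned.
#'
#' @param rect unit rectangle `c(x0, y0, x1, y1)`, mm.
#' @param phi line orientation, degrees.
#' @param spacing perpendicular line spacing, mm (> 0).
#' @return List of 2 x 2 matrices (rows = endpoints), ordered by signed
#'   offset from the centre line; each segment directed along
#'   (cos phi, sin phi).
#' @export
generate_unit_lines <- function(rect, phi, spacing) {
  ap_check(length(rect) == 4 && rect[3] > rect[1] && rect[4] > rect[2],
           "generate_unit_lines: `rect` must be c(x0, y0, x1, y1)")
  ap_check(spacing > 0, "generate_unit_lines: `spacing` must be > 0")
  unit_line_family(rect, phi, spacing, delta = 0)
}

#' Continuity-seeded print-line waypoint graph over an orientation field
#'
#' Discretizes every grid unit into print lines at the unit's local fiber
#' angle, chains each unit's lines into a serpentine polyline (one
#' continuous per-unit pass, the naive traversal baseline), densifies the
#' lines into waypoints, and connects waypoints of neighbouring units
#' whose positions on the shared border match within half the line
#' spacing.  Units are processed row-major from the lower-left unit, so
#' previously generated units seed the continuity of later ones.
#' Unequal line counts across a border simply leave the unmatched
#' endpoints unconnected (degree-1 nodes).
#'
#' @param field an [orientation_field()].
#' @param spacing perpendicular print-line spacing, mm.
#' @param waypoint_spacing target spacing between waypoints along a line,
#'   mm; each line keeps at least its two endpoints.
#' @param waypoints_per_unit if given, overrides `waypoint_spacing`: each
#'   unit receives exactly this many waypoints, allocated to its lines
#'   (two per line plus largest-remainder shares by length).
#' @param snap_tol border-matching tolerance, mm (default `spacing / 2`).
#' @return An object of class `waypoint_graph`: fields `x`, `y` (node
#'   coordinates), `unit` (grid-unit id per node), `edges` (m x 2 node
#'   indices), `unit_chains` (per-unit node sequences of the serpentine
#'   pass), `n_units`.
#' @export
generate_grid_lines <- function(field, spacing, waypoint_spacing = NULL,
                                waypoints_per_unit = NULL,
                                snap_tol = spacing / 2) {
  ap_check(inherits(field, "orientation_field"),
           "generate_grid_lines: `field` must be an orientation_field")
  ap_check(spacing > 0, "generate_grid_lines: `spacing` must be > 0")
  ap_check(!is.null(waypoint_spacing) || !is.null(waypoints_per_unit),
           "generate_grid_lines: give `waypoint_spacing` or `waypoints_per_unit`")
  nr <- nrow(field$angles); nc <- ncol(field$angles)
  xs <- numeric(0); ys <- numeric(0); unit <- integer(0)
  edges <- matrix(integer(0), 0, 2)
  unit_chains <- vector("list", nr * nc)
  avail <- integer(0)  # free serpentine-end node ids usable as seed points

  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    uid <- (i - 1L) * nc + j
    rect <- unit_rect(field, i, j)
    phi <- field$angles[i, j]
    # continuity seeding: free serpentine endpoints of the already
    # generated left/bottom neighbours, lying on the shared border, act
    # as potential starting points -- the line family is shifted by the
    # residual offset (at most half the spacing) so one line starts
    # exactly at the chosen seed point
    targets_id <- integer(0)
    if (j > 1L)
      targets_id <- c(targets_id, avail[unit[avail] == uid - 1L &
                                          abs(xs[avail] - rect[1]) <= 1e-6])
    if (i > 1L)
      targets_id <- c(targets_id, avail[unit[avail] == uid - nc &
                                          abs(ys[avail] - rect[2]) <= 1e-6])
    rad <- (phi %% 180) * pi / 180
    nv <- c(-sin(rad), cos(rad))
    ctr <- c((rect[1] + rect[3]) / 2, (rect[2] + rect[4]) / 2)
    hw <- (rect[3] - rect[1]) / 2; hh <- (rect[4] - rect[2]) / 2
    support <- hw * abs(nv[1]) + hh * abs(nv[2])
    K <- floor(support / spacing + 1e-9)
    delta <- 0
    anchor_id <- NA_integer_
    if (length(targets_id)) {
      off_t <- (xs[targets_id] - ctr[1]) * nv[1] + (ys[targets_id] - ctr[2]) * nv[2]
      k_near <- pmin(pmax(round(off_t / spacing), -K), K)
      resid <- off_t - k_near * spacing
      # only the outermost lines can start a serpentine
      elig <- abs(resid) <= snap_tol & (k_near == -K | k_near == K)
      if (any(elig)) {
        pick <- which(elig)[which.min(abs(resid[elig]))]
        delta <- resid[pick]
        anchor_id <- targets_id[pick]
      }
    }
    segs <- unit_line_family(rect, phi, spacing, delta)
    # orient the serpentine (line order and first direction) to start at
    # the seed point, or failing that nearest any available endpoint
    targets <- if (!is.na(anchor_id)) {
      cbind(xs[anchor_id], ys[anchor_id])
    } else if (length(targets_id)) {
      cbind(xs[targets_id], ys[targets_id])
    } else {
      matrix(numeric(0), 0, 2)
    }
    if (nrow(targets) && length(segs) > 0L) {
      nl <- length(segs)
      cand <- list(list(rev = FALSE, flip = FALSE, pt = segs[[1L]][1, ]),
                   list(rev = FALSE, flip = TRUE,  pt = segs[[1L]][2, ]),
                   list(rev = TRUE,  flip = FALSE, pt = segs[[nl]][1, ]),
                   list(rev = TRUE,  flip = TRUE,  pt = segs[[nl]][2, ]))
      dmin <- vapply(cand, function(cc) min(sqrt((targets[, 1] - cc$pt[1])^2 +
                                                   (targets[, 2] - cc$pt[2])^2)),
                     numeric(1))
      if (min(dmin) <= snap_tol) {
        pick <- cand[[which.min(dmin)]]
        if (pick$rev) segs <- rev(segs)
        if (pick$flip) segs[[1L]] <- segs[[1L]][2:1, ]
      }
    }
    pts_per_line <- allocate_waypoints(segs, waypoint_spacing, waypoints_per_unit)
    chain <- integer(0)
    prev_end <- NULL
    for (k in seq_along(segs)) {
      s <- segs[[k]]
      if (!is.null(prev_end)) {
        d0 <- sum((s[1, ] - prev_end)^2); d1 <- sum((s[2, ] - prev_end)^2)
        if (d1 < d0) s <- s[2:1, ]
      }
      np <- pts_per_line[k]
      t <- seq(0, 1, length.out = np)
      px <- s[1, 1] + t * (s[2, 1] - s[1, 1])
      py <- s[1, 2] + t * (s[2, 2] - s[1, 2])
      ids <- length(xs) + seq_len(np)
      xs <- c(xs, px); ys <- c(ys, py); unit <- c(unit, rep(uid, np))
      if (np > 1) edges <- rbind(edges, cbind(ids[-np], ids[-1]))
      if (length(chain)) edges <- rbind(edges, c(chain[length(chain)], ids[1]))
      chain <- c(chain, ids)
      prev_end <- s[2, ]
    }
    unit_chains[[uid]] <- chain
    # border snapping to the already-generated left and bottom neighbours:
    # only waypoints terminating ON the border (clipped line endpoints) are
    # junction candidates; candidates pair up within `snap_tol` along it
    near <- function(ids, coord, target) ids[abs(coord - target) <= 1e-6]
    mine_left   <- near(chain, xs[chain], rect[1])
    mine_bottom <- near(chain, ys[chain], rect[2])
    if (j > 1L) {
      nb <- unit_chains[[uid - 1L]]
      theirs <- near(nb, xs[nb], rect[1])
      edges <- rbind(edges, match_border(mine_left, theirs, xs, ys, snap_tol))
    }
    if (i > 1L) {
      nb <- unit_chains[[uid - nc]]
      theirs <- near(nb, ys[nb], rect[2])
      edges <- rbind(edges, match_border(mine_bottom, theirs, xs, ys, snap_tol))
    }
    # update the seed pool: the consumed seed and the new serpentine's
    # anchored start leave it; its free end (and start, if unanchored)
    # join it
    new_ends <- chain[c(1L, length(chain))]
    if (!is.na(anchor_id)) {
      avail <- setdiff(avail, anchor_id)
      coincident <- sqrt((xs[new_ends] - xs[anchor_id])^2 +
                           (ys[new_ends] - ys[anchor_id])^2) <= 1e-6
      new_ends <- new_ends[!coincident]
    }
    avail <- c(avail, new_ends)
  }
  new_waypoint_graph(xs, ys, unit, edges, unit_chains, nr * nc)
}

# parallel line family at orientation phi, pitch `spacing`, clipped to
# the rectangle; `delta` shifts the whole family along its normal
unit_line_family <- function(rect, phi, spacing, delta = 0) {
  rad <- (phi %% 180) * pi / 180
  u <- c(cos(rad), sin(rad))
  nv <- c(-sin(rad), cos(rad))
  cx <- (rect[1] + rect[3]) / 2; cy <- (rect[2] + rect[4]) / 2
  hw <- (rect[3] - rect[1]) / 2; hh <- (rect[4] - rect[2]) / 2
  support <- hw * abs(nv[1]) + hh * abs(nv[2])
  K <- floor(support / spacing + 1e-9)
  big <- 2 * (hw + hh) + spacing
  segs <- list()
  for (k in -K:K) {
    p <- c(cx, cy) + (k * spacing + delta) * nv
    s <- clip_segment_rect(p - big * u, p + big * u,
                           rect[1], rect[3], rect[2], rect[4])
    if (!is.null(s) && sqrt(sum((s[2, ] - s[1, ])^2)) > 1e-9)
      segs[[length(segs) + 1L]] <- s
  }
  segs
}

# waypoint budget per line: either from a target spacing or an exact
# per-unit count (>= 2 per line, remainder by line length)
allocate_waypoints <- function(segs, waypoint_spacing, waypoints_per_unit) {
  nl <- length(segs)
  lens <- vapply(segs, function(s) sqrt(sum((s[2, ] - s[1, ])^2)), numeric(1))
  if (is.null(waypoints_per_unit)) {
    return(pmax(2L, ceiling(lens / waypoint_spacing) + 1L))
  }
  N <- waypoints_per_unit
  ap_check(N >= 2L * nl,
           sprintf("generate_grid_lines: waypoints_per_unit = %d is too small for %d lines (need >= %d)",
                   N, nl, 2L * nl))
  base <- rep(2L, nl)
  extra <- N - 2L * nl
  share <- lens / sum(lens) * extra
  add <- floor(share)
  rem <- extra - sum(add)
  if (rem > 0) {
    ord <- order(share - add, -lens, decreasing = TRUE)
    add[ord[seq_len(rem)]] <- add[ord[seq_len(rem)]] + 1L
  }
  base + as.integer(add)
}

# greedy unique nearest matching between two border node sets
match_border <- function(mine, theirs, xs, ys, tol) {
  if (length(mine) == 0L || length(theirs) == 0L) return(matrix(integer(0), 0, 2))
  d <- outer(seq_along(mine), seq_along(theirs), function(a, b)
    sqrt((xs[mine[a]] - xs[theirs[b]])^2 + (ys[mine[a]] - ys[theirs[b]])^2))
  pairs <- which(d <= tol, arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(matrix(integer(0), 0, 2))
  ord <- order(d[pairs], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  used_m <- logical(length(mine)); used_t <- logical(length(theirs))
  out <- matrix(integer(0), 0, 2)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    if (!used_m[a] && !used_t[b]) {
      used_m[a] <- TRUE; used_t[b] <- TRUE
      out <- rbind(out, c(mine[a], theirs[b]))
    }
  }
  out
}

new_waypoint_graph <- function(xs, ys, unit, edges, unit_chains, n_units) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    ap_check(all(edges[, 1] != edges[, 2]), "waypoint_graph: self-loop edge")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  structure(list(x = xs, y = ys, unit = as.integer(unit), edges = edges,
                 unit_chains = unit_chains, n_units = n_units),
            class = "waypoint_graph")
}

#' @export
print.waypoint_graph <- function(x, ...) {
  cat(sprintf("Waypoint graph: %d nodes, %d edges, %d grid units\n",
              length(x$x), nrow(x$edges), x$n_units))
  invisible(x)
}

#' Trim a waypoint graph to a layer contour
#'
#' Removes nodes strictly outside the polygon (boundary points survive);
#' edges crossing the boundary are clipped with a new node inserted at
#' the first crossing, inheriting the interior endpoint's grid unit.
#'
#' @param graph a `waypoint_graph`.
#' @param contour simple polygon (n x 2 matrix, or a one-element list as
#'   returned by [layer_contour()]).
#' @return A trimmed `waypoint_graph` (possibly empty).
#' @export
trim_to_contour <- function(graph, contour) {
  ap_check(inherits(graph, "waypoint_graph"), "trim_to_contour: `graph` must be a waypoint_graph")
  if (is.list(contour) && !is.matrix(contour)) {
    ap_check(length(contour) >= 1, "trim_to_contour: empty contour list")
    contour <- contour[[1]]
  }
  contour <- as.matrix(contour)
  n <- length(graph$x)
  if (n == 0L) return(graph)
  inside <- point_in_polygon(graph$x, graph$y, contour)
  xs <- graph$x[inside]; ys <- graph$y[inside]
  unit <- graph$unit[inside]
  remap <- integer(n); remap[inside] <- seq_len(sum(inside))
  edges <- matrix(integer(0), 0, 2)
  for (r in seq_len(nrow(graph$edges))) {
    a <- graph$edges[r, 1]; b <- graph$edges[r, 2]
    if (inside[a] && inside[b]) {
      edges <- rbind(edges, c(remap[a], remap[b]))
    } else if (inside[a] || inside[b]) {
      if (!inside[a]) { tmp <- a; a <- b; b <- tmp }
      p0 <- c(graph$x[a], graph$y[a]); p1 <- c(graph$x[b], graph$y[b])
      ts <- segment_polygon_crossings(p0, p1, contour)
      if (length(ts)) {
        p <- p0 + ts[1] * (p1 - p0)
        xs <- c(xs, p[1]); ys <- c(ys, p[2]); unit <- c(unit, graph$unit[a])
        edges <- rbind(edges, c(remap[a], length(xs)))
      }
    }
  }
  chains <- lapply(graph$unit_chains, function(ch) {
    ch <- ch[inside[ch]]
    remap[ch]
  })
  new_waypoint_graph(xs, ys, unit, edges, chains, graph$n_units)
}
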