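#' Machine programs
#'
#' A machine program is an ordered table of motion/extrusion commands.
#' Each row is a straight move from the previous position to (x, y, z):
#' `feed` is the travel speed (mm/s), `flow` the volumetric extrusion
#' rate over that segment (mm^3/s, 0 on travel moves) and `extrude`
#' whether material is deposited.  Metadata (units, nozzle diameter,
#' default speed, per-section ink ids) is carried in the `meta`
#' attribute.
#'
#' @param commands data frame with columns `x`, `y`, `z`, `feed`,
#'   `flow`, `extrude`, `layer`, `role`, `ink`.
#' @param meta named list of header metadata.
#' @return An object of class `machine_program`.
#' @export
machine_program <- function(commands, meta = list()) {
  need <- c("x", "y", "z", "feed", "flow", "extrude", "layer", "role", "ink")
  ap_check(is.data.frame(commands) && all(need %in% names(commands)),
           paste0("machine_program: commands need columns ",
                  paste(need, collapse = ", ")))
  ap_check(all(is.finite(commands$x) & is.finite(commands$y) & is.finite(commands$z)),
           "machine_program: positions must be finite")
  ap_check(all(commands$feed > 0), "machine_program: feed must be > 0 on moves")
  ap_check(all(commands$flow >= 0), "machine_program: flow must be >= 0")
  ap_check(all(commands$flow[!commands$extrude] == 0),
           "machine_program: flow must be 0 when extrusion is off")
  structure(list(commands = commands, meta = meta), class = "machine_program")
}

#' @export
print.machine_program <- function(x, ...) {
  cm <- x$commands
  cat(sprintf("Machine program: %d commands (%d extruding), %d layers\n",
              nrow(cm), sum(cm$extrude), length(unique(cm$layer))))
  if (!is.null(x$meta$nozzle_d))
    cat(sprintf("  nozzle d = %g mm, speed = %g mm/s\n",
                x$meta$nozzle_d, x$meta$speed))
  cat(sprintf("  extruded volume = %.4g mm^3\n", extruded_volume(x)))
  invisible(x)
}

#' Total extruded volume of a program
#'
#' Sum over extruding segments of `flow * segment_time`.
#'
#' @param program a `machine_program`.
#' @return Volume in mm^3.
#' @export
extruded_volume <- function(program) {
  cm <- program$commands
  if (nrow(cm) < 2) return(0)
  d <- sqrt(diff(cm$x)^2 + diff(cm$y)^2 + diff(cm$z)^2)
  i <- which(cm$extrude[-1]) + 1L
  sum(cm$flow[i] * d[i - 1L] / cm$feed[i])
}

#' Plan a full conformal anisotropic print
#'
#' Composes the whole pipeline: (optional) reorientation of the part
#' mesh and extraction of its bottom template, conformal layering,
#' per-layer fiber-aligned print-line generation with alternating
#' 90-degree offsets between successive infill layers, contour trimming,
#' DFS path optimization, projection onto the layer surface,
#' inclination-compensated nozzle height and slaved volumetric flow, and
#' emission of an ordered machine program with travel moves between
#' paths.
#'
#' @param field an [orientation_field()] giving the in-plane fiber
#'   directions for infill layers.
#' @param voxel a [voxel_spec()]; the nozzle diameter is taken as `w1`
#'   and the infill line pitch as `L2`.
#' @param layer_plan data frame `(role, thickness)` as for
#'   [conformal_layers()].
#' @param mesh optional [tri_mesh()] of the part; when given it is
#'   reoriented for minimal height, its bottom surface becomes the
#'   conformal template and each layer is trimmed to the part contour.
#'   Without a mesh a flat substrate spanning the field is used.
#' @param options named list of overrides: `speed` (mm/s, default
#'   16.667), `seed` (default 1), `restarts` (default 100),
#'   `waypoint_spacing` (mm, default `unit_size / 4`), `grid_spacing`
#'   (template grid, mm, default 1), `sign_convention` (see
#'   [adjust_nozzle_height()]), `reorient` (default TRUE),
#'   `sacrificial_ink` (default "pluronic"), `structural_ink`
#'   (default "silicone").
#' @return A [machine_program()].
#' @export
plan_print <- function(field, voxel, layer_plan, mesh = NULL, options = list()) {
  ap_check(inherits(field, "orientation_field"), "plan_print: `field` must be an orientation_field")
  ap_check(inherits(voxel, "voxel_spec"), "plan_print: `voxel` must be a voxel_spec")
  opt <- modifyList(list(speed = 16.667, seed = 1L, restarts = 100L,
                         waypoint_spacing = field$unit_size / 4,
                         grid_spacing = 1, sign_convention = "descending_plus",
                         reorient = TRUE, sacrificial_ink = "pluronic",
                         structural_ink = "silicone"), options)
  d <- voxel$w1
  pitch <- voxel$L2

  if (!is.null(mesh)) {
    ap_check(inherits(mesh, "tri_mesh"), "plan_print: `mesh` must be a tri_mesh")
    if (isTRUE(opt$reorient)) mesh <- reorient_min_height(mesh)$mesh
    sp <- suppressWarnings(split_top_bottom(mesh))
    bot <- mesh$vertices[sp$bottom$vertex_idx, , drop = FALSE]
    base <- tryCatch(
      heightfield_from_points(bot, opt$grid_spacing),
      error = function(e) flat_base(field))
  } else {
    base <- flat_base(field)
  }
  layers <- conformal_layers(base, layer_plan)

  rows <- list()
  infill_count <- 0L
  for (layer in layers) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) stop(sprintf(
        "plan_print: stage `%s` failed at layer %d: %s",
        what, layer$index, conditionMessage(e)), call. = FALSE))
    }
    if (layer$role == "infill") {
      infill_count <- infill_count + 1L
      lf <- if (infill_count %% 2L == 0L) rotate_field(field, 90) else field
      sp_line <- pitch
      ink <- opt$structural_ink
    } else {
      # full infill: constant direction alternating with layer parity
      ang <- if (layer$index %% 2L == 0L) 90 else 0
      lf <- langer_field(ncol(field$angles), nrow(field$angles), "constant",
                         unit_size = field$unit_size, angle = ang,
                         origin = field$origin)
      sp_line <- d
      ink <- if (layer$role == "sacrificial") opt$sacrificial_ink else opt$structural_ink
    }
    graph <- stage("generate_grid_lines",
                   generate_grid_lines(lf, spacing = sp_line,
                                       waypoint_spacing = opt$waypoint_spacing))
    if (!is.null(mesh)) {
      cont <- stage("layer_contour", layer_contour(mesh, layer))
      if (length(cont) == 0L) next
      graph <- stage("trim_to_contour", trim_to_contour(graph, cont[[1]]))
      if (length(graph$x) == 0L) next
    }
    ps <- stage("optimize_paths",
                optimize_paths(graph, restarts = opt$restarts,
                               seed = opt$seed + layer$index))
    h0 <- layer$thickness
    for (p in ps$paths) {
      # shared border junctions are coincident node pairs; collapse them
      if (length(p) > 1L) {
        dup <- c(FALSE, abs(diff(graph$x[p])) < 1e-9 &
                   abs(diff(graph$y[p])) < 1e-9)
        p <- p[!dup]
      }
      p3 <- stage("project_to_surface",
                  project_to_surface(cbind(graph$x[p], graph$y[p]), layer))
      np <- nrow(p3)
      if (np >= 2) {
        gr <- stage("path_gradient", path_gradient(p3))
        h <- stage("adjust_nozzle_height",
                   adjust_nozzle_height(h0, d, gr$alpha, gr$sense,
                                        sign_convention = opt$sign_convention))
      } else {
        h <- h0
      }
      # nozzle z includes the inclination compensation relative to h0
      zcmd <- p3[, 3] + (h - h0)
      # per-segment flow: slaved to the mean adjusted height of the segment
      hseg <- if (np >= 2) (h[-np] + h[-1]) / 2 else h
      qseg <- flow_rate(opt$speed, d, hseg)
      rows[[length(rows) + 1L]] <- data.frame(
        x = p3[, 1], y = p3[, 2], z = zcmd,
        feed = opt$speed,
        flow = c(0, if (np >= 2) qseg else NULL),
        extrude = c(FALSE, rep(TRUE, np - 1L)),
        layer = layer$index, role = layer$role, ink = ink)
    }
  }
  ap_check(length(rows) > 0, "plan_print: empty program (no layer intersects the part)")
  cmds <- do.call(rbind, rows)
  rownames(cmds) <- NULL
  machine_program(cmds, meta = list(
    units = "mm", nozzle_d = d, speed = opt$speed, seed = opt$seed,
    pitch = pitch, inks = unique(cmds$ink)))
}

flat_base <- function(field) {
  ext_x <- field$origin[1] + c(0, ncol(field$angles) * field$unit_size)
  ext_y <- field$origin[2] + c(0, nrow(field$angles) * field$unit_size)
  heightfield_from_function(function(x, y) 0 * x, ext_x, ext_y,
                            spacing = field$unit_size / 4)
}

#' Write a machine program
#'
#' Two dialects: `generic_gcode` emits `G0` travel and `G1` extrusion
#' moves with `E` as cumulative extruded volume (mm^3), `F` in mm/min
#' and the segment flow in a trailing `;Q:` comment; `command_csv` is a
#' headered table of the command data frame.  Both round-trip through
#' [read_machine_program()] exactly at the 6-decimal precision they are
#' written with.
#'
#' @param program a `machine_program`.
#' @param path output file.
#' @param dialect `"generic_gcode"` or `"command_csv"`.
#' @return `path`, invisibly.
#' @export
write_gcode <- function(program, path, dialect = c("generic_gcode", "command_csv")) {
  dialect <- match.arg(dialect)
  ap_check(inherits(program, "machine_program"), "write_gcode: `program` must be a machine_program")
  cm <- program$commands
  r6 <- function(v) sprintf("%.6f", round(v, 6))
  if (dialect == "command_csv") {
    out <- data.frame(x = r6(cm$x), y = r6(cm$y), z = r6(cm$z),
                      feed = r6(cm$feed), flow = r6(cm$flow),
                      extrude = as.integer(cm$extrude),
                      layer = cm$layer, role = cm$role, ink = cm$ink)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  lines <- c(sprintf("; anisoprint program, units=%s nozzle_d=%s speed=%s",
                     program$meta$units %||% "mm",
                     ap_num(program$meta$nozzle_d %||% NA),
                     ap_num(program$meta$speed %||% NA)))
  if (nrow(cm)) {
    dist <- c(0, sqrt(diff(cm$x)^2 + diff(cm$y)^2 + diff(cm$z)^2))
    dvol <- ifelse(cm$extrude, round(cm$flow, 6) * dist / cm$feed, 0)
    E <- cumsum(dvol)
    lines <- c(lines, ifelse(
      cm$extrude,
      sprintf("G1 X%s Y%s Z%s E%s F%s ;Q:%s", r6(cm$x), r6(cm$y), r6(cm$z),
              sprintf("%.9f", E), r6(cm$feed * 60), r6(cm$flow)),
      sprintf("G0 X%s Y%s Z%s F%s", r6(cm$x), r6(cm$y), r6(cm$z),
              r6(cm$feed * 60))))
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a machine program written by [write_gcode()]
#'
#' @param path file path.
#' @param dialect dialect the file was written in.
#' @return A `machine_program` (the `layer`, `role` and `ink` columns
#'   are recovered for `command_csv`; the G-code dialect fills them with
#'   placeholders).
#' @export
read_machine_program <- function(path, dialect = c("generic_gcode", "command_csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "command_csv") {
    cm <- utils::read.csv(path)
    cm$extrude <- cm$extrude == 1
    return(machine_program(cm, meta = list(units = "mm")))
  }
  lines <- readLines(path)
  mv <- grep("^G[01] ", lines, value = TRUE)
  if (length(mv) == 0L) {
    return(machine_program(data.frame(x = numeric(0), y = numeric(0),
                                      z = numeric(0), feed = numeric(0),
                                      flow = numeric(0), extrude = logical(0),
                                      layer = integer(0), role = character(0),
                                      ink = character(0)),
                           meta = list(units = "mm")))
  }
  getv <- function(tag) {
    v <- rep(NA_real_, length(mv))
    hit <- regexpr(paste0(tag, "(-?[0-9.]+)"), mv)
    has <- hit > 0
    v[has] <- as.numeric(sub(tag, "", regmatches(mv, hit)))
    v
  }
  x <- getv("X"); y <- getv("Y"); z <- getv("Z"); f <- getv("F")
  q <- getv("Q:")
  extrude <- startsWith(mv, "G1")
  q[!extrude | is.na(q)] <- 0
  machine_program(data.frame(x = x, y = y, z = z, feed = f / 60, flow = q,
                             extrude = extrude, layer = NA_integer_,
                             role = "unknown", ink = "unknown"),
                  meta = list(units = "mm"))
}
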