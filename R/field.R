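#' Orientation fields
#'
#' An orientation field assigns a dominant fiber angle (degrees, reduced
#' modulo 180) to every unit of a regular grid.  Row 1 is the bottom row
#' of units; column 1 the leftmost.  `unit_size` is the side length of a
#' grid unit in mm.
#'
#' @param angles numeric matrix of angles in degrees (rows = y units
#'   bottom-up, cols = x units left-right); reduced modulo 180.
#' @param unit_size unit side length, mm (> 0).
#' @param origin XY position of the lower-left corner, mm.
#' @return An object of class `orientation_field`.
#' @export
orientation_field <- function(angles, unit_size, origin = c(0, 0)) {
  angles <- as.matrix(angles)
  ap_check(is.numeric(angles) && all(is.finite(angles)),
           "orientation_field: `angles` must be a finite numeric matrix")
  ap_check(nrow(angles) >= 1 && ncol(angles) >= 1,
           "orientation_field: grid dimensions must be >= 1")
  ap_check(is.numeric(unit_size) && unit_size > 0,
           "orientation_field: `unit_size` must be > 0")
  structure(list(angles = angles %% 180, unit_size = unit_size,
                 origin = as.numeric(origin)),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("Orientation field: %d x %d units of %g mm, angles in [%.3g, %.3g) deg\n",
              nrow(x$angles), ncol(x$angles), x$unit_size,
              min(x$angles), max(x$angles)))
  invisible(x)
}

#' Generate a synthetic fiber-orientation field
#'
#' Stand-in for imaging-derived collagen-axis maps.  Three modes:
#' `constant` (every unit gets `angle`), `random` (i.i.d. uniform on
#' [0, 180)), and `langer_sine`, a smooth dermal-line-like pattern
#' \deqn{\phi(x) = \mathrm{angle} + \mathrm{amplitude}\,
#'       \sin(2\pi x_c / \mathrm{period})} evaluated at the unit-centre
#' x coordinate (constant along y), reduced modulo 180.
#'
#' @param n number of unit columns (x direction).
#' @param m number of unit rows (y direction).
#' @param mode `"constant"`, `"random"` or `"langer_sine"`.
#' @param seed integer seed (used by `random`); the global RNG state is
#'   restored afterwards.
#' @param unit_size unit side length, mm.
#' @param angle base angle, degrees (default 0).
#' @param amplitude sine amplitude, degrees (default 30).
#' @param period sine period, mm (default: the field's x extent).
#' @param origin lower-left corner, mm.
#' @return An `orientation_field` with `m` rows and `n` columns.
#' @export
langer_field <- function(n, m, mode = c("constant", "random", "langer_sine"),
                         seed = 1L, unit_size = 10, angle = 0, amplitude = 30,
                         period = NULL, origin = c(0, 0)) {
  mode <- match.arg(mode)
  ap_check(n >= 1 && m >= 1, "langer_field: grid dimensions must be >= 1")
  ang <- switch(mode,
    constant = matrix(angle, m, n),
    random = ap_with_seed(seed, matrix(stats::runif(m * n, 0, 180), m, n)),
    langer_sine = {
      if (is.null(period)) period <- n * unit_size
      xc <- origin[1] + (seq_len(n) - 0.5) * unit_size
      matrix(angle + amplitude * sin(2 * pi * xc / period), m, n, byrow = TRUE)
    })
  orientation_field(ang, unit_size, origin)
}

# evaluate code with a fixed seed, restoring the caller's RNG state
ap_with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Read or write an orientation field as CSV
#'
#' The CSV is a headerless numeric grid of angles in degrees whose first
#' row is the TOP row of units (natural reading order); metadata
#' (`unit_size`, `origin`) travel in a `#`-prefixed comment line.
#'
#' @param path file path.
#' @param field an `orientation_field`.
#' @return `read_orientation_field()` returns an `orientation_field`.
#' @export
read_orientation_field <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  unit_size <- 10; origin <- c(0, 0)
  if (length(meta)) {
    kv <- strsplit(sub("^#\\s*", "", meta[1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(kv))
    if (length(vals) >= 1 && !is.na(vals[1])) unit_size <- vals[1]
    if (length(vals) >= 3 && !anyNA(vals[2:3])) origin <- vals[2:3]
  }
  body <- lines[!startsWith(lines, "#")]
  m <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
  orientation_field(m[rev(seq_len(nrow(m))), , drop = FALSE], unit_size, origin)
}

#' @rdname read_orientation_field
#' @export
write_orientation_field <- function(field, path) {
  ap_check(inherits(field, "orientation_field"),
           "write_orientation_field: `field` must be an orientation_field")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %.9g %.9g %.9g", field$unit_size,
                     field$origin[1], field$origin[2]), con)
  a <- field$angles[rev(seq_len(nrow(field$angles))), , drop = FALSE]
  writeLines(apply(a, 1, function(r) paste(format(r, trim = TRUE), collapse = ",")), con)
  invisible(path)
}

# unit rectangle (x0, y0, x1, y1) of unit (row i, col j)
unit_rect <- function(field, i, j) {
  u <- field$unit_size
  c(field$origin[1] + (j - 1) * u, field$origin[2] + (i - 1) * u,
    field$origin[1] + j * u, field$origin[2] + i * u)
}

# rotate all angles by 90 degrees (alternate-layer orthogonal lattice)
rotate_field <- function(field, deg = 90) {
  orientation_field(field$angles + deg, field$unit_size, field$origin)
}
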