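#' Inverse design: find a printable voxel with a target anisotropy
#'
#' Searches the voxel parameter space for a spec whose predicted
#' anisotropic ratio matches `target_gamma`, restricted to the printable
#' region of an optional spanning-width model.  Print-line widths are
#' pinned to the nozzle diameter (`w1 = w2 = d`, the flow-controlled
#' operating point) and the print-line spacings of alternating layers are
#' kept equal (`s1 = s2 = s`, so `L1 = L2 = d + s`).  The remaining free
#' parameters are the print heights `h1`, `h2` and the spacing `s`; any of
#' them may be pinned through `fixed`.
#'
#' The search is deterministic: free secondary parameters are scanned on a
#' fixed grid (ordered so that taller layers -- fewer layers per part,
#' hence shorter print time -- are tried first) and the primary parameter
#' (`h1` if free, else `h2`, else `s`) is solved by bisection, exploiting
#' the monotonicity of gamma along each axis.  If no candidate reaches the
#' target, an error of class `anisoprint_infeasible_design` is signalled
#' carrying the achievable `gamma_range`.
#'
#' @param target_gamma desired anisotropic ratio (> 0).
#' @param fixed named list; must contain `d` (nozzle diameter, mm), `E1`
#'   and `E2` (kPa); may pin `h1`, `h2`, `s` (mm).
#' @param constraints optional [fit_spanning_model()] fit restricting
#'   (h/d, s/d) to the printable region (applied to both layers).
#' @param tol relative tolerance on the achieved gamma (default 1e-3).
#' @param h_bounds,s_bounds search bounds as multiples of `d`; defaults
#'   `c(0.2, 1.25)` for heights and `c(0.1, 1)` for the spacing.
#' @return A [voxel_spec()] with attribute `gamma_achieved`.
#' @examples
#' v <- design_voxel(1.5, fixed = list(d = 0.84, E1 = 100, E2 = 100))
#' predict_anisotropy(v)$gamma
#' @export
design_voxel <- function(target_gamma, fixed, constraints = NULL, tol = 1e-3,
                         h_bounds = c(0.2, 1.25), s_bounds = c(0.1, 1)) {
  ap_check(is.numeric(target_gamma) && length(target_gamma) == 1L && target_gamma > 0,
           "design_voxel: `target_gamma` must be a positive scalar")
  ap_check(is.list(fixed) && all(c("d", "E1", "E2") %in% names(fixed)),
           "design_voxel: `fixed` must provide at least `d`, `E1` and `E2`")
  ap_check(is.null(constraints) || inherits(constraints, "spanning_model"),
           "design_voxel: `constraints` must be NULL or a spanning_model")
  d <- fixed$d
  ap_check(d > 0, "design_voxel: `d` must be positive")

  hb <- h_bounds * d
  sb <- s_bounds * d
  spec_of <- function(h1, h2, s) {
    voxel_spec(w1 = d, w2 = d, h1 = h1, h2 = h2,
               L1 = d + s, L2 = d + s, E1 = fixed$E1, E2 = fixed$E2)
  }
  gamma_of <- function(h1, h2, s) predict_anisotropy(spec_of(h1, h2, s))$gamma
  ok <- function(h1, h2, s) {
    is.null(constraints) ||
      (is_printable(constraints, h1 / d, s / d) &&
         is_printable(constraints, h2 / d, s / d))
  }

  free <- setdiff(c("h1", "h2", "s"), names(fixed))
  if (length(free) == 0L) {
    spec <- spec_of(fixed$h1, fixed$h2, fixed$s)
    g <- predict_anisotropy(spec)$gamma
    if (abs(g - target_gamma) <= tol * target_gamma && ok(fixed$h1, fixed$h2, fixed$s)) {
      attr(spec, "gamma_achieved") <- g
      return(spec)
    }
    stop_infeasible(target_gamma, c(g, g))
  }
  primary <- free[1]
  grid_of <- function(var) {
    if (var %in% names(fixed)) return(fixed[[var]])
    b <- if (var == "s") sb else hb
    g <- seq(b[1], b[2], length.out = 9)
    if (var == "h2") rev(g) else g  # taller h2 first: fewer layers
  }
  prim_bounds <- if (primary == "s") sb else hb

  h2_cands <- grid_of("h2")
  s_cands  <- grid_of("s")
  h1_cands <- grid_of("h1")

  best <- NULL
  gseen <- c(Inf, -Inf)
  for (s in s_cands) for (h2 in h2_cands) for (h1 in h1_cands) {
    # the primary variable's candidate value is ignored; it is solved for
    if (primary == "h1" && h1 != h1_cands[1]) next
    if (primary == "h2" && h2 != h2_cands[1]) next
    if (primary == "s"  && s  != s_cands[1])  next
    val <- list(h1 = h1, h2 = h2, s = s)
    f <- function(x) {
      val[[primary]] <- x
      gamma_of(val$h1, val$h2, val$s) - target_gamma
    }
    feas <- function(x) { val[[primary]] <- x; ok(val$h1, val$h2, val$s) }
    # restrict the primary interval to its printable sub-range
    xs <- seq(prim_bounds[1], prim_bounds[2], length.out = 41)
    xs <- xs[vapply(xs, feas, logical(1))]
    if (length(xs) < 2L) next
    lo <- min(xs); hi <- max(xs)
    flo <- f(lo); fhi <- f(hi)
    gseen[1] <- min(gseen[1], flo + target_gamma, fhi + target_gamma)
    gseen[2] <- max(gseen[2], flo + target_gamma, fhi + target_gamma)
    root <- if (abs(flo) <= tol * target_gamma) lo
            else if (abs(fhi) <= tol * target_gamma) hi
            else if (flo * fhi < 0)
              stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
            else NULL
    if (is.null(root)) next
    val[[primary]] <- root
    cand <- list(h1 = val$h1, h2 = val$h2, s = val$s,
                 layers_score = val$h1 + val$h2)
    if (is.null(best) || cand$layers_score > best$layers_score + 1e-12) best <- cand
  }
  if (is.null(best)) stop_infeasible(target_gamma, gseen)
  spec <- spec_of(best$h1, best$h2, best$s)
  attr(spec, "gamma_achieved") <- predict_anisotropy(spec)$gamma
  spec
}

stop_infeasible <- function(target_gamma, gamma_range) {
  gamma_range <- sort(gamma_range)
  cond <- structure(
    class = c("anisoprint_infeasible_design", "error", "condition"),
    list(message = sprintf(
      "design_voxel: target gamma = %g is outside the achievable range [%.4g, %.4g]",
      target_gamma, gamma_range[1], gamma_range[2]),
      call = NULL, gamma_range = gamma_range))
  stop(cond)
}
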