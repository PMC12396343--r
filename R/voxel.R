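#' Specify an orthogonal two-line infill voxel
#'
#' The repeating unit of the anisotropic infill lattice consists of one
#' print-line segment from each of two orthogonal layers plus the gaps
#' between neighbouring lines.  Layer 1 lines run along the longitudinal
#' axis with width `w1`, height `h1`, pitch `L1` (centre-to-centre distance
#' between layer-1 lines, measured along the transverse axis is `L2`; see
#' Details) and constituent modulus `E1`; layer 2 is the orthogonal layer.
#'
#' @details The pitches couple across layers: the spacing between layer-1
#'   lines is `s1 = L2 - w1` and between layer-2 lines `s2 = L1 - w2`, so
#'   printability requires `w1 <= L2` and `w2 <= L1`.  Print lines are
#'   idealized as rectangular in cross-section; real filaments extruded
#'   from a cylindrical nozzle are rounded, which this model deliberately
#'   ignores.
#'
#' @param w1,w2 print-line widths, mm.
#' @param h1,h2 print-line heights, mm.
#' @param L1,L2 voxel pitches, mm.
#' @param E1,E2 constituent elastic moduli, kPa.
#' @return An object of class `voxel_spec`.
#' @examples
#' v <- voxel_spec(w1 = 0.84, w2 = 0.84, h1 = 0.84, h2 = 0.42,
#'                 L1 = 1.14, L2 = 1.14, E1 = 100, E2 = 100)
#' predict_anisotropy(v)
#' @export
voxel_spec <- function(w1, w2, h1, h2, L1, L2, E1, E2) {
  v <- list(w1 = w1, w2 = w2, h1 = h1, h2 = h2,
            L1 = L1, L2 = L2, E1 = E1, E2 = E2)
  for (f in names(v)) {
    ap_check(is.numeric(v[[f]]) && length(v[[f]]) == 1L && is.finite(v[[f]]),
             paste0("voxel_spec: `", f, "` must be a finite numeric scalar"))
    ap_check(v[[f]] > 0, paste0("voxel_spec: `", f, "` must be strictly positive"))
  }
  ap_check(w1 <= L2, "voxel_spec: invariant w1 <= L2 violated (spacing s1 = L2 - w1 < 0)")
  ap_check(w2 <= L1, "voxel_spec: invariant w2 <= L1 violated (spacing s2 = L1 - w2 < 0)")
  structure(v, class = "voxel_spec")
}

#' @export
print.voxel_spec <- function(x, ...) {
  cat("Voxel spec (mm, kPa):\n")
  cat(sprintf("  layer 1: w = %g, h = %g, pitch L1 = %g, E1 = %g\n",
              x$w1, x$h1, x$L1, x$E1))
  cat(sprintf("  layer 2: w = %g, h = %g, pitch L2 = %g, E2 = %g\n",
              x$w2, x$h2, x$L2, x$E2))
  cat(sprintf("  spacings: s1 = %g, s2 = %g\n", x$L2 - x$w1, x$L1 - x$w2))
  invisible(x)
}

#' Constituent volumes of one voxel
#'
#' Decomposes the voxel bounding box into the two line volumes and the two
#' gap volumes:
#' \deqn{V_{L1} = w_1 h_1 L_1,\quad V_{L2} = w_2 h_2 L_2,}
#' \deqn{V_{S1} = L_1 h_1 (L_2 - w_1),\quad V_{S2} = L_2 h_2 (L_1 - w_2),}
#' \deqn{V_B = L_1 L_2 (h_1 + h_2).}
#' The decomposition is exact: `VL1 + VS1 + VL2 + VS2 == VB`.
#'
#' @param spec a [voxel_spec()].
#' @return An object of class `volume_fractions` with fields `VL1`, `VL2`,
#'   `VS1`, `VS2`, `VB` (mm^3).
#' @export
volume_fractions <- function(spec) {
  ap_check(inherits(spec, "voxel_spec"), "volume_fractions: `spec` must be a voxel_spec")
  out <- list(
    VL1 = spec$w1 * spec$h1 * spec$L1,
    VL2 = spec$w2 * spec$h2 * spec$L2,
    VS1 = spec$L1 * spec$h1 * (spec$L2 - spec$w1),
    VS2 = spec$L2 * spec$h2 * (spec$L1 - spec$w2),
    VB  = spec$L1 * spec$L2 * (spec$h1 + spec$h2))
  structure(out, class = "volume_fractions")
}

#' @export
print.volume_fractions <- function(x, ...) {
  cat(sprintf("Voxel volumes (mm^3): VL1 = %g, VS1 = %g, VL2 = %g, VS2 = %g, VB = %g\n",
              x$VL1, x$VS1, x$VL2, x$VS2, x$VB))
  invisible(x)
}

#' Predict the apparent moduli and anisotropic ratio of a voxel lattice
#'
#' Homogenizes the orthogonal two-line voxel into apparent elastic moduli
#' along the two print-line axes.  Loading along layer-1 lines puts those
#' lines in parallel (iso-strain) with the layer-2 sublaminate, whose line
#' and gap volumes act in series through the spanning sections:
#' \deqn{E_L = \frac{V_{L1} E_1\,[V_{L1} E_1 + (V_{S2}+V_{L2}) E_2]}
#'                  {V_B\,[V_{L1} E_1 + V_{S2} E_2]}}
#' and \eqn{E_T} is the same expression with all layer-1 and layer-2
#' quantities exchanged.  The anisotropic ratio is \eqn{\gamma = E_L/E_T}.
#' With zero spacings both expressions reduce to the Voigt rule of
#' mixtures \eqn{(V_{L1}E_1 + V_{L2}E_2)/V_B}.
#'
#' @param spec a [voxel_spec()].
#' @return An object of class `elastic_anisotropy` with fields `EL`, `ET`
#'   (kPa) and `gamma`.
#' @export
predict_anisotropy <- function(spec) {
  v <- volume_fractions(spec)
  E1 <- spec$E1; E2 <- spec$E2
  den_L <- v$VB * (v$VL1 * E1 + v$VS2 * E2)
  den_T <- v$VB * (v$VL2 * E2 + v$VS1 * E1)
  ap_check(den_L > 0 && den_T > 0,
           "predict_anisotropy: degenerate voxel (zero volume denominator)")
  EL <- v$VL1 * E1 * (v$VL1 * E1 + (v$VS2 + v$VL2) * E2) / den_L
  ET <- v$VL2 * E2 * (v$VL2 * E2 + (v$VS1 + v$VL1) * E1) / den_T
  structure(list(EL = EL, ET = ET, gamma = EL / ET),
            class = "elastic_anisotropy")
}

#' @export
print.elastic_anisotropy <- function(x, ...) {
  cat(sprintf("Apparent moduli: EL = %.4g kPa, ET = %.4g kPa, gamma = %.4g\n",
              x$EL, x$ET, x$gamma))
  invisible(x)
}

#' Anisotropic ratio measured off-axis
#'
#' Apparent anisotropic ratio when the measurement axes are rotated by
#' `phi` degrees relative to the print-line axes (equal print-line
#' spacings in alternating layers assumed).  The default `ellipse_sqrt`
#' form is
#' \deqn{\gamma(\phi) = \sqrt{\frac{E_L^2\cos^2\phi + E_T^2\sin^2\phi}
#'                                 {E_L^2\sin^2\phi + E_T^2\cos^2\phi}}}
#' which satisfies \eqn{\gamma(0) = E_L/E_T}, \eqn{\gamma(45^\circ) = 1}
#' and the reciprocity \eqn{\gamma(\phi)\gamma(\phi+90^\circ) = 1}.  The
#' alternative `linear_mix` form interpolates the moduli themselves,
#' \eqn{(E_L\cos^2\phi + E_T\sin^2\phi)/(E_L\sin^2\phi + E_T\cos^2\phi)};
#' both forms agree at 0, 45 and 90 degrees.
#'
#' @param aniso an `elastic_anisotropy` (or a [voxel_spec()], which is
#'   homogenized first).
#' @param phi angle(s) in degrees; reduced modulo 180.
#' @param form `"ellipse_sqrt"` (default) or `"linear_mix"`.
#' @return `gamma(phi)`, same length as `phi`.
#' @export
anisotropy_at_angle <- function(aniso, phi, form = c("ellipse_sqrt", "linear_mix")) {
  form <- match.arg(form)
  if (inherits(aniso, "voxel_spec")) aniso <- predict_anisotropy(aniso)
  ap_check(inherits(aniso, "elastic_anisotropy"),
           "anisotropy_at_angle: `aniso` must be an elastic_anisotropy or voxel_spec")
  ap_check(is.numeric(phi) && all(is.finite(phi)),
           "anisotropy_at_angle: `phi` must be numeric")
  rad <- (phi %% 180) * pi / 180
  c2 <- cos(rad)^2; s2 <- sin(rad)^2
  if (form == "ellipse_sqrt") {
    sqrt((aniso$EL^2 * c2 + aniso$ET^2 * s2) /
         (aniso$EL^2 * s2 + aniso$ET^2 * c2))
  } else {
    (aniso$EL * c2 + aniso$ET * s2) / (aniso$EL * s2 + aniso$ET * c2)
  }
}

#' Read or write a voxel specification as JSON
#'
#' The JSON schema is a flat object with numeric fields `w1, w2, h1, h2,
#' L1, L2, E1, E2` (mm and kPa).
#'
#' @param path file path.
#' @param spec a [voxel_spec()].
#' @return `read_voxel_spec()` returns a `voxel_spec`;
#'   `write_voxel_spec()` returns `path` invisibly.
#' @export
read_voxel_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("w1", "w2", "h1", "h2", "L1", "L2", "E1", "E2")
  miss <- setdiff(need, names(x))
  ap_check(length(miss) == 0,
           paste0("read_voxel_spec: missing fields: ", paste(miss, collapse = ", ")))
  do.call(voxel_spec, as.list(x[need]))
}

#' @rdname read_voxel_spec
#' @export
write_voxel_spec <- function(spec, path) {
  ap_check(inherits(spec, "voxel_spec"), "write_voxel_spec: `spec` must be a voxel_spec")
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
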