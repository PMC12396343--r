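#' Volume of a spherical fluid capsule
#'
#' \deqn{v_c = \tfrac{4}{3}\pi r_c^3} with the radius in micrometres and
#' the volume reported in microlitres.  Full precision is returned;
#' round only for display (the conventional report uses 3 significant
#' figures).
#'
#' @param rc capsule radius, micrometres (> 0); vectorized.
#' @return Capsule volume, microlitres.
#' @examples
#' signif(capsule_volume(337.5), 3)  # 0.161
#' @export
capsule_volume <- function(rc) {
  ap_check(is.numeric(rc) && all(rc > 0), "capsule_volume: `rc` must be > 0")
  (4 / 3) * pi * (rc / 1000)^3  # mm^3 == microlitre
}

#' Plan a capsule loading for a target volume fraction
#'
#' Computes how many capsules of radius `rc` realize a `fraction_vv`
#' volumetric loading.  Two referencing conventions exist: in the
#' gel-referenced convention (default, matching loading capsules on top
#' of a solidified carrier gel) `carrier_volume` is the gel portion and
#' the capsule volume is `carrier * f / (1 - f)`; in the
#' suspension-referenced convention `carrier_volume` is the total
#' suspension and the capsule volume is `carrier * f`.
#'
#' @param carrier_volume carrier volume, microlitres.
#' @param fraction_vv target capsule volume fraction, in (0, 1).
#' @param rc capsule radius, micrometres.
#' @param convention `"gel"` (default) or `"suspension"`.
#' @return List of class `loading_plan`: `n_capsules`,
#'   `capsule_total_volume` (microlitres; the realized volume
#'   `n_capsules * vc`), `target_capsule_volume`, `vc`, `convention`.
#' @examples
#' loading_plan(800, 0.2, 337.5)  # 200 ul of capsules
#' @export
loading_plan <- function(carrier_volume, fraction_vv, rc,
                         convention = c("gel", "suspension")) {
  convention <- match.arg(convention)
  ap_check(carrier_volume > 0, "loading_plan: `carrier_volume` must be > 0")
  ap_check(fraction_vv > 0 && fraction_vv < 1,
           "loading_plan: `fraction_vv` must lie in (0, 1)")
  vc <- capsule_volume(rc)
  target <- if (convention == "gel") {
    carrier_volume * fraction_vv / (1 - fraction_vv)
  } else {
    carrier_volume * fraction_vv
  }
  n <- floor(target / vc)
  structure(list(n_capsules = n,
                 capsule_total_volume = n * vc,
                 target_capsule_volume = target,
                 vc = vc, convention = convention),
            class = "loading_plan")
}

#' @export
print.loading_plan <- function(x, ...) {
  cat(sprintf("Loading plan (%s-referenced): %d capsules of %.3g ul (total %.4g ul, target %.4g ul)\n",
              x$convention, x$n_capsules, signif(x$vc, 3),
              x$capsule_total_volume, x$target_capsule_volume))
  invisible(x)
}

#' Capsule contact diameter from a compression trace
#'
#' The diameter of a capsule compressed between parallel plates is the
#' largest plate gap at which the compression force first rises markedly
#' above its pre-contact baseline.  The baseline is the force at the
#' widest gaps; "marked" means exceeding baseline by `rise_threshold`
#' (default: 5 times the estimated pre-contact force SD).
#'
#' @param trace data frame with columns `gap` (mm, strictly decreasing)
#'   and `force` (N).
#' @param rise_threshold force rise, N, above the pre-contact baseline;
#'   `NULL` (default) uses 5 x the SD of the first quarter of the trace.
#' @return Contact diameter, mm.
#' @export
contact_diameter <- function(trace, rise_threshold = NULL) {
  ap_check(is.data.frame(trace) && all(c("gap", "force") %in% names(trace)),
           "contact_diameter: need columns `gap` and `force`")
  ap_check(all(diff(trace$gap) < 0), "contact_diameter: `gap` must be strictly decreasing")
  n <- nrow(trace)
  pre <- seq_len(max(3L, floor(n / 4)))
  baseline <- stats::median(trace$force[pre])
  if (is.null(rise_threshold)) {
    s <- stats::sd(trace$force[pre])
    rise_threshold <- 5 * max(s, .Machine$double.eps)
  }
  hit <- which(trace$force > baseline + rise_threshold)
  ap_check(length(hit) > 0, "contact_diameter: no contact detected")
  trace$gap[hit[1]]
}

#' Read a compression trace from CSV
#'
#' Expects headered columns `gap` (mm) and `force` (N).
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_compression_trace <- function(path) {
  tr <- utils::read.csv(path)
  ap_check(all(c("gap", "force") %in% names(tr)),
           "read_compression_trace: need columns gap, force")
  tr
}
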