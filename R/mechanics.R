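#' Tangent modulus from a stress-strain curve
#'
#' Fits a fourth-degree polynomial to the stress-strain curve by ordinary
#' least squares and returns the tangent (first derivative) at
#' `eval_strain`.  This mirrors the standard tensile-test reduction for
#' soft silicones, where the small-strain tangent is taken at 5% strain.
#'
#' @param curve a data frame with numeric columns `strain` (dimensionless,
#'   strictly increasing, starting at 0) and `stress` (kPa), with at least
#'   5 rows; see [read_stress_strain()].
#' @param eval_strain strain at which the tangent is evaluated (default
#'   0.05); must lie within the curve's strain range.
#' @return Tangent modulus in kPa.
#' @examples
#' eps <- seq(0, 0.4, length.out = 50)
#' modulus_from_curve(data.frame(strain = eps, stress = 100 * eps))  # 100
#' @export
modulus_from_curve <- function(curve, eval_strain = 0.05) {
  curve <- validate_stress_strain(curve)
  ap_check(eval_strain >= min(curve$strain) && eval_strain <= max(curve$strain),
           "modulus_from_curve: `eval_strain` outside the curve's strain range")
  fit <- stats::lm(stress ~ strain + I(strain^2) + I(strain^3) + I(strain^4),
                   data = curve)
  b <- stats::coef(fit)
  # derivative of b0 + b1 e + b2 e^2 + b3 e^3 + b4 e^4
  unname(b[2] + 2 * b[3] * eval_strain + 3 * b[4] * eval_strain^2 +
           4 * b[5] * eval_strain^3)
}

validate_stress_strain <- function(curve) {
  ap_check(is.data.frame(curve) && all(c("strain", "stress") %in% names(curve)),
           "stress-strain curve: need columns `strain` and `stress`")
  ap_check(nrow(curve) >= 5,
           "stress-strain curve: at least 5 points required (degree-4 fit is underdetermined)")
  ap_check(all(diff(curve$strain) > 0),
           "stress-strain curve: `strain` must be strictly increasing")
  ap_check(abs(curve$strain[1]) < 1e-9,
           "stress-strain curve: `strain` must start at 0")
  curve
}

#' Read a stress-strain curve from CSV
#'
#' Expects a headered CSV with columns `strain` (dimensionless) and
#' `stress` (kPa).
#'
#' @param path file path.
#' @return A validated data frame.
#' @export
read_stress_strain <- function(path) {
  validate_stress_strain(utils::read.csv(path))
}

#' Fit the spanning-width printability surface
#'
#' When a print line spans the gap between lines of the layer below, its
#' width narrows by cohesion.  The relative width `w1/w0` of the spanning
#' section is modelled as a full bivariate quadratic in the normalized
#' print height `h/d` and print-line spacing `s/d`:
#' \deqn{w_1/w_0 = c_0 + c_1 x + c_2 y + c_3 x^2 + c_4 x y + c_5 y^2,
#'       \quad x = h/d,\ y = s/d,}
#' fitted by ordinary least squares.  Predictions are clamped to [0, 1].
#' The fitted surface defines the printable region: parameter
#' combinations whose predicted narrowing stays above a threshold.
#'
#' @param measurements data frame with columns `h_over_d`, `s_over_d`,
#'   `w_ratio` (= w1/w0); at least 6 distinct (h/d, s/d) points.
#' @param d nozzle inner diameter, mm.
#' @param threshold minimum acceptable relative width, in (0, 1]
#'   (default 0.5, the 50%-narrowing cutting plane).
#' @param w0 unreduced print-line width, mm; defaults to `d` (flow is
#'   controlled so the extruded width equals the nozzle diameter).
#' @return An object of class `spanning_model` with the 6 coefficients.
#' @seealso [predict.spanning_model()], [is_printable()]
#' @export
fit_spanning_model <- function(measurements, d, threshold = 0.5, w0 = d) {
  ap_check(is.data.frame(measurements) &&
             all(c("h_over_d", "s_over_d", "w_ratio") %in% names(measurements)),
           "fit_spanning_model: need columns h_over_d, s_over_d, w_ratio")
  pts <- unique(measurements[, c("h_over_d", "s_over_d")])
  ap_check(nrow(pts) >= 6,
           "fit_spanning_model: at least 6 distinct (h/d, s/d) points required")
  ap_check(is.numeric(d) && d > 0, "fit_spanning_model: `d` must be positive")
  ap_check(is.numeric(threshold) && threshold > 0 && threshold <= 1,
           "fit_spanning_model: `threshold` must lie in (0, 1]")
  x <- measurements$h_over_d; y <- measurements$s_over_d
  X <- cbind(1, x, y, x^2, x * y, y^2)
  qrX <- qr(X)
  ap_check(qrX$rank == 6L,
           "fit_spanning_model: rank-deficient design matrix (points not in general position)")
  cf <- qr.coef(qrX, measurements$w_ratio)
  structure(list(coefficients = unname(cf), d = d, w0 = w0,
                 threshold = threshold),
            class = "spanning_model")
}

#' Predict relative spanning width
#'
#' @param object a [fit_spanning_model()] fit.
#' @param h_over_d,s_over_d normalized print height and spacing.
#' @param clamp clamp predictions to [0, 1] (default TRUE).
#' @param ... unused.
#' @return Predicted `w1/w0`, clamped to [0, 1].
#' @export
predict.spanning_model <- function(object, h_over_d, s_over_d, clamp = TRUE, ...) {
  cf <- object$coefficients
  p <- cf[1] + cf[2] * h_over_d + cf[3] * s_over_d +
    cf[4] * h_over_d^2 + cf[5] * h_over_d * s_over_d + cf[6] * s_over_d^2
  if (clamp) p <- pmin(1, pmax(0, p))
  p
}

#' Printability test under the spanning model
#'
#' Two published forms of the 50% criterion exist: a bound on the relative
#' narrowing `w1/w0` and a bound on the absolute normalized width `w1/d =
#' (w1/w0) * (w0/d)`.  With the usual choice `w0 = d` the two coincide;
#' both accessors are provided.
#'
#' @param model a `spanning_model`.
#' @param h_over_d,s_over_d normalized print height and spacing.
#' @param criterion `"w1_over_d"` (default) or `"w1_over_w0"`.
#' @return Logical vector.
#' @export
is_printable <- function(model, h_over_d, s_over_d,
                         criterion = c("w1_over_d", "w1_over_w0")) {
  criterion <- match.arg(criterion)
  ap_check(inherits(model, "spanning_model"), "is_printable: `model` must be a spanning_model")
  p <- predict(model, h_over_d, s_over_d)
  if (criterion == "w1_over_d") {
    p * model$w0 / model$d >= model$threshold
  } else {
    p >= model$threshold
  }
}

#' @export
print.spanning_model <- function(x, ...) {
  cf <- x$coefficients
  cat("Spanning-width quadratic surface, w1/w0 = f(h/d, s/d):\n")
  cat(sprintf("  %.4g + %.4g x + %.4g y + %.4g x^2 + %.4g xy + %.4g y^2\n",
              cf[1], cf[2], cf[3], cf[4], cf[5], cf[6]))
  cat(sprintf("  d = %g mm, w0 = %g mm, threshold = %g\n", x$d, x$w0, x$threshold))
  invisible(x)
}

#' Read a spanning-width measurement table from CSV
#'
#' Expects headered columns `h_over_d`, `s_over_d`, `w_ratio`.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_spanning_table <- function(path) {
  m <- utils::read.csv(path)
  ap_check(all(c("h_over_d", "s_over_d", "w_ratio") %in% names(m)),
           "read_spanning_table: need columns h_over_d, s_over_d, w_ratio")
  m
}
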