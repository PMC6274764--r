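# Linear concentration-signal calibrations. Both optical channels of the
# assay obey Beer-Lambert-type linearity over the working range: absorbance
# at 515 nm and fluorescence at 670 nm (420 nm excitation) are affine in dye
# concentration, so ordinary least squares with intercept is the model.

#' Ordinary least-squares calibration fit
#'
#' Wraps [stats::lm()] (response ~ predictor, with intercept) and reports the
#' quantities a calibration consumer needs: slope, intercept, R-squared
#' (1 - SS_res / SS_tot), residuals. Intercepts are fitted rather than forced
#' through the origin because blank subtraction is imperfect under noise.
#'
#' @param x predictor values (e.g. concentration in mM), not all equal,
#'   length >= 3.
#' @param y response values (signal units), same length.
#' @param xlab,ylab axis labels carried into reports.
#' @return An object of class `calibration_fit`.
#' @export
fit_linear <- function(x, y, xlab = "x", ylab = "y") {
  if (length(x) != length(y) || length(x) < 3)
    .user_error("calibration needs >= 3 (x, y) points of equal length",
                "osteem_domain_error")
  if (diff(range(x)) == 0)
    .user_error("degenerate predictor: all x values equal",
                "osteem_domain_error")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  res <- stats::residuals(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(res^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_points = length(x),
                 residuals = unname(res), x = x, y = y,
                 xlab = xlab, ylab = ylab, model = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Linear calibration: %s = %.6g * %s + %.6g\n",
              x$ylab, x$slope, x$xlab, x$intercept))
  cat(sprintf("  n = %d, R-squared = %.6f\n", x$n_points, x$r_squared))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.calibration_fit <- function(object, ...) object$residuals

#' @export
summary.calibration_fit <- function(object, ...) {
  s <- summary(object$model)
  cat(sprintf("Calibration of %s against %s\n", object$ylab, object$xlab))
  print.calibration_fit(object)
  cat(sprintf("  residual sd = %.4g\n", s$sigma))
  invisible(s)
}

#' @export
predict.calibration_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(stats::fitted(object$model))
  object$intercept + object$slope * newdata
}

#' @export
plot.calibration_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = x$xlab, ylab = x$ylab,
                 pch = 19, log = "", ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("R² = %.4f", x$r_squared))
  invisible(x)
}

#' Calibration of the absorbance channel (OD at 515 nm vs concentration)
#'
#' @param series a [dilution_series()].
#' @param blank blank [od_spectrum()] for subtraction.
#' @return A `calibration_fit` of blank-subtracted OD\@515 against mM.
#' @export
calibrate_od <- function(series, blank) {
  stopifnot(inherits(series, "dilution_series"))
  y <- vapply(series$samples, function(s) od_value(s$od, blank), numeric(1))
  fit_linear(series$concentrations_mM, y,
             xlab = "concentration_mM", ylab = "od_515")
}

#' Calibration of the fluorescence channel (F670 at 420 nm excitation)
#'
#' @param series a [dilution_series()].
#' @return A `calibration_fit` of I(exc 420, em 670) against mM.
#' @export
calibrate_fluorescence <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  y <- vapply(series$samples, function(s) get_intensity(s$eem, 420, 670),
              numeric(1))
  fit_linear(series$concentrations_mM, y,
             xlab = "concentration_mM", ylab = "f670_exc420")
}

#' Cross-calibration of fluorescence against absorbance
#'
#' Relates the two channels directly across a dilution series: F670
#' (420 nm excitation) fitted against blank-subtracted OD\@515.
#'
#' @inheritParams calibrate_od
#' @return A `calibration_fit` (signal per signal).
#' @export
cross_calibrate <- function(series, blank) {
  stopifnot(inherits(series, "dilution_series"))
  x <- vapply(series$samples, function(s) od_value(s$od, blank), numeric(1))
  y <- vapply(series$samples, function(s) get_intensity(s$eem, 420, 670),
              numeric(1))
  fit_linear(x, y, xlab = "od_515", ylab = "f670_exc420")
}

#' Inverse prediction from a calibration fit
#'
#' @param fit a `calibration_fit` with nonzero slope.
#' @param signal observed signal value(s).
#' @return Predicted concentration(s) `(signal - intercept) / slope`;
#'   negative predictions are reported as-is with attribute
#'   `below_range = TRUE`.
#' @export
predict_concentration <- function(fit, signal) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0)
    .user_error("cannot invert a zero-slope calibration",
                "osteem_domain_error")
  out <- (signal - fit$intercept) / fit$slope
  if (any(out < 0)) attr(out, "below_range") <- TRUE
  out
}

#' Calibration report table
#'
#' @param fits named list of `calibration_fit`s (names = channel labels).
#' @return data.frame with columns channel, slope, intercept, r_squared,
#'   n_points.
#' @export
calibration_report <- function(fits) {
  do.call(rbind, lapply(names(fits), function(ch) {
    f <- fits[[ch]]
    data.frame(channel = ch, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, n_points = f$n_points,
               stringsAsFactors = FALSE)
  }))
}
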