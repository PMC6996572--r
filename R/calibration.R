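# Native-mass calibration: a single log-linear (Ferguson-style) fit of
# log10(mass) on slice position, the standard choice for blue-native gels.

#' Fit the slice-to-mass calibration curve
#'
#' Ordinary least squares of `log10(mass_kda)` on `slice_center` over the
#' complex/supercomplex standards. At least three standards are required and
#' the fitted slope must be negative (large species run near the top of the
#' gel, slice 1); a non-negative slope indicates an inverted gel orientation
#' and is an error.
#'
#' @param standards a [StandardsTable].
#' @return A [CalibrationCurve] with intercept, slope, residual standard
#'   deviation (in log10 kDa) and the number of standards used.
#' @examples
#' st <- StandardsTable(data.frame(name = c("a", "b", "c"),
#'                                 slice_center = c(10, 20, 30),
#'                                 mass_kda = c(1000, 100, 10)))
#' fitCalibration(st)
#' @export
fitCalibration <- function(standards) {
  d <- standardsData(standards)
  if (nrow(d) < 3L)
    cplxError("calibration needs at least 3 standards",
              "cplx_underdetermined_error")
  fit <- lm(log10(mass_kda) ~ slice_center, data = d)
  b <- unname(coef(fit)[2])
  if (!is.finite(b) || b >= 0)
    cplxError(
      "fitted slope is non-negative: inverted gel orientation (mass must decrease with slice)",
      "cplx_orientation_error")
  rsd <- if (nrow(d) > 2L) sqrt(sum(fit$residuals^2) / (nrow(d) - 2L)) else 0
  CalibrationCurve(intercept = unname(coef(fit)[1]), slope = b,
                   residualSd = rsd, nStandards = nrow(d))
}

#' Convert between slice position and native mass
#'
#' `massAt()` evaluates the calibration at a (possibly fractional) slice
#' position and returns the apparent native mass in kDa; `sliceAt()` is its
#' exact inverse. `massAt()` is strictly decreasing in slice.
#'
#' @param curve a [CalibrationCurve].
#' @param slice numeric slice position(s).
#' @param massKda positive native mass(es) in kDa.
#' @return numeric vector of masses (kDa) or fractional slice positions.
#' @examples
#' curve <- CalibrationCurve(4.0, -0.1)
#' massAt(curve, 15)       # 10^2.5 = 316.23 kDa
#' sliceAt(curve, 1000)    # 10
#' @export
massAt <- function(curve, slice) {
  10^(curve@intercept + curve@slope * slice)
}

#' @rdname massAt
#' @export
sliceAt <- function(curve, massKda) {
  if (any(massKda <= 0))
    cplxError("mass query must be positive", "cplx_validation_error")
  (log10(massKda) - curve@intercept) / curve@slope
}

#' Slice interval covering a mass window
#'
#' Translates a relative mass window `[center * (1 - tol), center * (1 + tol)]`
#' into the corresponding slice interval `(lo, hi)` (fractional bounds,
#' lo < hi since mass decreases with slice), clipped to `[1, nSlices]`.
#' A degenerate window (narrower than half a slice, i.e. below the slice
#' sampling resolution) is widened to one slice with a warning.
#' Used for windowed peak quantification, e.g. the area of a module trace at
#' the mass of the fully assembled complex.
#'
#' @param curve a [CalibrationCurve].
#' @param centerKda window center in kDa.
#' @param toleranceFraction half-width of the window as a fraction of the
#'   center mass (default 0.10).
#' @param nSlices number of slices to clip to (default 64).
#' @return numeric `c(lo, hi)` fractional slice bounds.
#' @export
massWindowToSlices <- function(curve, centerKda, toleranceFraction = 0.10,
                               nSlices = 64L) {
  if (toleranceFraction <= 0 || toleranceFraction >= 1)
    cplxError("toleranceFraction must be in (0, 1)", "cplx_validation_error")
  lo <- sliceAt(curve, centerKda * (1 + toleranceFraction))
  hi <- sliceAt(curve, centerKda * (1 - toleranceFraction))
  # below half the slice sampling the window is degenerate for integration
  if (hi - lo < 0.5) {
    warning(sprintf(
      "mass window around %.4g kDa spans %.2f slices; widening to 1 slice",
      centerKda, hi - lo), call. = FALSE)
    mid <- (lo + hi) / 2
    lo <- mid - 0.5
    hi <- mid + 0.5
  }
  lo <- max(1, min(lo, nSlices))
  hi <- max(1, min(hi, nSlices))
  c(lo = lo, hi = hi)
}
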