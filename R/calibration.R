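#' @include derivative.R
NULL

#' Select a zero-crossing measurement wavelength
#'
#' Implements the zero-crossing rule: analyte A is measured where the
#' interferent B's first-derivative amplitude is concentration-stable at
#' zero, provided A itself retains usable signal there. Candidate
#' wavelengths are the non-edge grid points plus the interpolated zero
#' crossings of every interferent trace, restricted to those where the
#' analyte reference |1D| is at least \code{sensitivityFloor} times its
#' maximum. Among the candidates, the wavelength minimising the
#' worst-case relative interference -- the largest interferent |1D|
#' across the panel divided by the analyte reference |1D| at that
#' wavelength, i.e. the worst concentration bias the interferent can
#' cause -- is chosen; ties are broken towards the strongest analyte
#' signal. Normalising by the analyte's own sensitivity is what keeps the
#' choice at the interferent's zero crossing rather than at a remote band
#' tail, where the interferent's amplitude is also numerically small but
#' the analyte's sensitivity is poor; including the interpolated
#' crossings makes the measured interferent contribution vanish
#' identically there for noiseless spectra of any concentration. With no
#' interferent signal anywhere the rule degenerates to the
#' floor-constrained argmax of the analyte's |1D|.
#'
#' @param interferentDerivs list of \linkS4class{DerivSpectrum} of the pure
#'   interferent at several (>= 3 recommended) concentrations.
#' @param analyteDeriv reference \linkS4class{DerivSpectrum} of the pure
#'   analyte.
#' @param sensitivityFloor fraction in [0, 1).
#' @return measurement wavelength, nm.
#' @export
selectMeasurementWavelength <- function(interferentDerivs, analyteDeriv,
                                        sensitivityFloor = 0.2) {
  if (is(interferentDerivs, "DerivSpectrum"))
    interferentDerivs <- list(interferentDerivs)
  stopifnot(length(interferentDerivs) >= 1L, is(analyteDeriv, "DerivSpectrum"))
  w <- analyteDeriv@wavelengths
  for (d in interferentDerivs)
    if (!isTRUE(all.equal(d@wavelengths, w)))
      dataError("interferent and analyte derivative spectra must share a grid")
  e <- analyteDeriv@meta$edge
  if (is.null(e)) e <- (analyteDeriv@interval - 1L) %/% 2L
  core <- (e + 1L):(length(w) - e)
  crossings <- unique(unlist(lapply(interferentDerivs, findZeroCrossings)))
  cand <- sort(c(w[core], crossings))
  ref <- abs(interpUniform(w, analyteDeriv@amplitudes, cand))
  feas <- cand[ref >= sensitivityFloor * max(ref)]
  if (!length(feas))
    numericError("channels unresolvable at this delta-lambda: no wavelength retains %g of the analyte's maximum |1D|",
                 sensitivityFloor)
  refFeas <- ref[match(feas, cand)]
  worst <- rep(0, length(feas))
  for (d in interferentDerivs)
    worst <- pmax(worst, abs(interpUniform(w, d@amplitudes, feas)))
  worst <- worst / refFeas
  best <- min(worst)
  tied <- which(worst <= best + 1e-12 * (best + 1))
  feas[tied[which.max(refFeas[tied])]]
}

#' Fit a calibration curve
#'
#' Ordinary least squares of signed 1D amplitude on concentration. When a
#' replicate structure is supplied, the pooled fit provides the working
#' slope/intercept/r2 and each replicate's points are refitted separately;
#' the standard deviation of those per-replicate intercepts is stored as
#' \code{sigmaIntercept}, the sigma of the ICH detection-limit formulas.
#' With fewer than two replicate curves it is flagged unavailable
#' (\code{NA}).
#'
#' @param concentrations ug/mL; >= 3 distinct values required.
#' @param amplitudes signed 1D amplitudes, same length.
#' @param replicates optional replicate id per point.
#' @param analyte,wavelength annotation stored on the curve.
#' @return a \linkS4class{CalibrationCurve}.
#' @examples
#' fitCalibration(c(0, 1, 2), c(1, 3, 5))  # slope 2, intercept 1, r = 1
#' @export
fitCalibration <- function(concentrations, amplitudes, replicates = NULL,
                           analyte = NA_character_, wavelength = NA_real_) {
  if (length(concentrations) != length(amplitudes))
    dataError("'concentrations' and 'amplitudes' must have equal length")
  if (length(unique(concentrations)) < 3L)
    dataError("calibration needs >= 3 distinct concentration levels")
  fit <- stats::lm(amplitudes ~ concentrations)
  co <- stats::coef(fit)
  r <- stats::cor(concentrations, amplitudes)
  sigma <- NA_real_
  if (!is.null(replicates)) {
    groups <- split(seq_along(amplitudes), replicates)
    ints <- vapply(groups, function(i) {
      if (length(unique(concentrations[i])) < 2L) return(NA_real_)
      stats::coef(stats::lm(amplitudes[i] ~ concentrations[i]))[[1]]
    }, numeric(1))
    ints <- ints[!is.na(ints)]
    if (length(ints) >= 2L) sigma <- stats::sd(ints)
  }
  new("CalibrationCurve",
      analyte = as.character(analyte), wavelength = as.numeric(wavelength),
      slope = co[[2]], intercept = co[[1]],
      r = r, rSquared = r^2, sigmaIntercept = sigma,
      rangeLow = min(concentrations), rangeHigh = max(concentrations),
      n = length(amplitudes))
}

#' Inverse prediction from a calibration curve
#'
#' \code{C = (amplitude - intercept) / slope}. Predictions outside the
#' curve's validated range carry an \code{outOfRange} attribute (logical,
#' one per prediction); there is no silent extrapolation.
#'
#' @param curve a \linkS4class{CalibrationCurve}.
#' @param amplitude signed 1D amplitude(s).
#' @return numeric ug/mL with attribute \code{outOfRange}.
#' @examples
#' curve <- new("CalibrationCurve", analyte = "ATO", wavelength = 384,
#'              slope = 0.2138, intercept = 3.9893, r = 0.9999,
#'              rSquared = 0.9998, sigmaIntercept = NA_real_,
#'              rangeLow = 0.4, rangeHigh = 6, n = 6L)
#' predictConcentration(curve, 4.4169)  # 2.0 ug/mL
#' @export
predictConcentration <- function(curve, amplitude) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (curve@slope == 0)
    numericError("calibration slope is zero; concentration is undefined")
  conc <- (amplitude - curve@intercept) / curve@slope
  flag <- conc < curve@rangeLow | conc > curve@rangeHigh
  structure(conc, outOfRange = flag)
}

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve '%s' at %.2f nm over %g-%g ug/mL (n = %d)\n",
    object@analyte, object@wavelength, object@rangeLow, object@rangeHigh,
    object@n))
  cat(sprintf("  1D = %.4f C %s %.4f,  r = %.4f, r2 = %.4f, sigma(intercept) = %s\n",
              object@slope, if (object@intercept < 0) "-" else "+",
              abs(object@intercept), object@r, object@rSquared,
              if (is.na(object@sigmaIntercept)) "unavailable"
              else format(object@sigmaIntercept, digits = 4)))
})
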