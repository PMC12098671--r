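#' @include syncspec.R
NULL

#' First derivative of a synchronous spectrum
#'
#' Default mode is a Savitzky-Golay first derivative (polynomial order 2,
#' window = \code{interval} points), scaled to AFU/nm using the grid step;
#' the filter's polynomial edge fit keeps the output the same length as
#' the input. The alternative \code{"lagged"} mode is a plain central
#' difference over the same point gap, matching instrument software that
#' implements "data interval" as a differentiation gap rather than a
#' smoothing window. Amplitudes are signed: positive where the intensity
#' rises with wavelength.
#'
#' @param spectrum a \linkS4class{SyncSpectrum} (any
#'   \linkS4class{FluorSpectrum} is accepted).
#' @param interval odd window size in points, \code{3 <= interval <=
#'   length/2}.
#' @param mode \code{"savgol"} (default) or \code{"lagged"}.
#' @return a \linkS4class{DerivSpectrum}; its \code{meta$edge} records how
#'   many points at each end are edge-fitted and therefore excluded from
#'   zero-crossing searches.
#' @export
firstDerivative <- function(spectrum, interval = 15, mode = c("savgol", "lagged")) {
  stopifnot(is(spectrum, "FluorSpectrum"))
  mode <- match.arg(mode)
  interval <- as.integer(interval)
  n <- length(spectrum@wavelengths)
  if (interval %% 2L == 0L || interval < 3L)
    dataError("derivative interval must be an odd integer >= 3 (got %d)", interval)
  if (interval > n / 2)
    dataError("spectrum too short (%d points) for a %d-point derivative window",
              n, interval)
  step <- gridStep(spectrum@wavelengths)
  y <- spectrum@intensities
  if (mode == "savgol") {
    amp <- signal::sgolayfilt(y, p = 2, n = interval, m = 1, ts = step)
  } else {
    h <- (interval - 1L) %/% 2L
    amp <- rep(NA_real_, n)
    core <- (h + 1L):(n - h)
    amp[core] <- (y[core + h] - y[core - h]) / (2 * h * step)
    amp[seq_len(h)] <- amp[h + 1L]
    amp[(n - h + 1L):n] <- amp[n - h]
  }
  meta <- spectrum@meta
  meta$deltaLambda <- if (is(spectrum, "SyncSpectrum")) spectrum@deltaLambda else NA_real_
  meta$step <- step
  meta$mode <- mode
  meta$edge <- (interval - 1L) %/% 2L
  new("DerivSpectrum", wavelengths = spectrum@wavelengths,
      amplitudes = as.numeric(amp), interval = interval, meta = meta)
}

#' Locate zero crossings of a derivative spectrum
#'
#' Scans adjacent samples for sign changes and refines each crossing by
#' linear interpolation between the bracketing samples. Edge-fitted points
#' (half a window at each end) are excluded. A crossing is suppressed when
#' the flanking |amplitude| on both sides is below \code{minFlank} (noise
#' guard). Exact zero samples count as crossings when a true sign change
#' surrounds them.
#'
#' @param deriv a \linkS4class{DerivSpectrum}.
#' @param minFlank noise guard, AFU/nm; >= 0.
#' @return numeric vector of crossing wavelengths in nm (possibly empty).
#' @export
findZeroCrossings <- function(deriv, minFlank = 0) {
  stopifnot(is(deriv, "DerivSpectrum"))
  if (minFlank < 0) dataError("'minFlank' must be >= 0")
  w <- deriv@wavelengths
  a <- deriv@amplitudes
  e <- deriv@meta$edge
  if (is.null(e)) e <- (deriv@interval - 1L) %/% 2L
  lo <- e + 1L
  hi <- length(a) - e
  if (hi - lo < 1L) return(numeric(0))
  out <- numeric(0)
  for (i in lo:(hi - 1L)) {
    a1 <- a[i]; a2 <- a[i + 1L]
    if (is.na(a1) || is.na(a2)) next
    if (a1 == 0 && a2 == 0) next
    if (a1 * a2 < 0 || (a1 == 0 && i > lo && a[i - 1L] * a2 < 0)) {
      if (abs(a1) < minFlank && abs(a2) < minFlank) next
      x <- if (a1 == 0) w[i] else w[i] + (w[i + 1L] - w[i]) * a1 / (a1 - a2)
      out <- c(out, x)
    }
  }
  out
}

#' Interpolated derivative amplitude at a wavelength
#'
#' Linear interpolation between the neighbouring samples; the signed value
#' is returned, since calibration consumes signed 1D amplitudes.
#'
#' @param deriv a \linkS4class{DerivSpectrum}.
#' @param wavelength query wavelength, nm; must lie inside the spectrum.
#' @return signed amplitude, AFU/nm.
#' @export
amplitudeAt <- function(deriv, wavelength) {
  stopifnot(is(deriv, "DerivSpectrum"))
  w <- deriv@wavelengths
  if (any(wavelength < w[1] | wavelength > w[length(w)]))
    dataError("wavelength %g nm is outside the spectrum range %s",
              wavelength[which(wavelength < w[1] | wavelength > w[length(w)])][1],
              fmtRange(w[1], w[length(w)]))
  interpUniform(w, deriv@amplitudes, wavelength)
}
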