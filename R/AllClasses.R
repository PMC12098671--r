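#' @include AllGenerics.R
NULL

#' Gaussian band model for a single fluorophore
#'
#' A fluorophore is described by symmetric Gaussian excitation and emission
#' bands: centre wavelengths \code{exMax}/\code{emMax} (nm), band standard
#' deviations \code{exWidth}/\code{emWidth} (nm), and \code{brightness}, the
#' intensity in arbitrary fluorescence units (AFU) per (ug/mL) when both
#' monochromators sit exactly on the band maxima. A positive Stokes shift
#' (\code{emMax > exMax}) is enforced.
#'
#' @slot name analyte name.
#' @slot exMax,emMax excitation / emission band maxima, nm.
#' @slot exWidth,emWidth Gaussian SD of each band, nm; strictly positive.
#' @slot brightness AFU per (ug/mL) at the band maxima; non-negative.
#' @seealso [fluorophore()], [defaultModels()], [bandIntensity()]
#' @export
setClass("Fluorophore",
  representation(
    name = "character",
    exMax = "numeric", emMax = "numeric",
    exWidth = "numeric", emWidth = "numeric",
    brightness = "numeric"
  )
)

setValidity("Fluorophore", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  for (s in c("exMax", "emMax", "exWidth", "emWidth", "brightness"))
    if (!num1(slot(object, s))) msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  if (length(msg)) return(msg)
  if (object@exWidth <= 0) msg <- c(msg, "'exWidth' must be > 0")
  if (object@emWidth <= 0) msg <- c(msg, "'emWidth' must be > 0")
  if (object@brightness < 0) msg <- c(msg, "'brightness' must be >= 0")
  if (object@emMax <= object@exMax)
    msg <- c(msg, "'emMax' must exceed 'exMax' (positive Stokes shift)")
  if (length(msg)) msg else TRUE
})

#' Instrument noise model
#'
#' Replicate noise applied to simulated intensities: independent additive
#' Gaussian noise (\code{additiveSd}, AFU) plus proportional Gaussian noise
#' (\code{proportionalCv}, a dimensionless fraction of the local noiseless
#' intensity). Both zero means a noiseless instrument.
#'
#' @slot additiveSd additive noise SD, AFU; >= 0.
#' @slot proportionalCv proportional noise CV (fraction); >= 0.
#' @seealso [noiseModel()], [defaultNoise()]
#' @export
setClass("NoiseModel",
  representation(additiveSd = "numeric", proportionalCv = "numeric")
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (length(object@additiveSd) != 1L || !is.finite(object@additiveSd) ||
      object@additiveSd < 0)
    msg <- c(msg, "'additiveSd' must be a single number >= 0")
  if (length(object@proportionalCv) != 1L || !is.finite(object@proportionalCv) ||
      object@proportionalCv < 0)
    msg <- c(msg, "'proportionalCv' must be a single number >= 0")
  if (length(msg)) msg else TRUE
})

#' Excitation-emission matrix
#'
#' Fluorescence intensity over the outer grid of excitation x emission
#' wavelengths. Both axes are strictly ascending, uniformly spaced nm
#' vectors; the intensity matrix is indexed \code{[ex, em]}. \code{meta}
#' carries provenance: the sample's concentrations, background level,
#' replicate id and seed when simulated, or the source file when read.
#'
#' @slot exWavelengths,emWavelengths wavelength axes, nm.
#' @slot intensities matrix of AFU, \code{length(ex) x length(em)}.
#' @slot meta named list of provenance.
#' @seealso [simulateEEM()], [synchronousSpectrum()], [readEEMCsv()]
#' @export
setClass("EEM",
  representation(
    exWavelengths = "numeric",
    emWavelengths = "numeric",
    intensities = "matrix",
    meta = "list"
  )
)

.checkGrid <- function(w, what) {
  if (length(w) < 2L) return(sprintf("'%s' needs >= 2 points", what))
  if (any(!is.finite(w))) return(sprintf("'%s' has non-finite values", what))
  d <- diff(w)
  if (any(d <= 0)) return(sprintf("'%s' must be strictly ascending", what))
  if (max(d) - min(d) > 1e-6 * mean(d))
    return(sprintf("'%s' must be uniformly spaced", what))
  NULL
}

setValidity("EEM", function(object) {
  msg <- c(
    .checkGrid(object@exWavelengths, "exWavelengths"),
    .checkGrid(object@emWavelengths, "emWavelengths")
  )
  if (!identical(dim(object@intensities),
                 c(length(object@exWavelengths), length(object@emWavelengths))))
    msg <- c(msg, "intensity matrix dimensions must match the two wavelength grids")
  if (any(!is.finite(object@intensities)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' One-dimensional fluorescence spectrum
#'
#' A trace of intensity against wavelength. \code{axisKind} records what the
#' wavelength axis means: a plain \code{"emission"} or \code{"excitation"}
#' scan, or \code{"synchronous-emission"} for a constant delta-lambda
#' synchronous trace reported on the emission axis (only the
#' \linkS4class{SyncSpectrum} subclass may carry that kind).
#'
#' @slot axisKind one of \code{"emission"}, \code{"excitation"},
#'   \code{"synchronous-emission"}.
#' @slot wavelengths strictly ascending nm axis.
#' @slot intensities AFU, same length as \code{wavelengths}.
#' @slot meta named list (sample id, units, ...).
#' @seealso [readSpectrumCsv()], [synchronousSpectrum()]
#' @export
setClass("FluorSpectrum",
  representation(
    axisKind = "character",
    wavelengths = "numeric",
    intensities = "numeric",
    meta = "list"
  )
)

setValidity("FluorSpectrum", function(object) {
  msg <- character()
  kinds <- c("emission", "excitation", "synchronous-emission")
  if (length(object@axisKind) != 1L || !object@axisKind %in% kinds)
    msg <- c(msg, paste0("'axisKind' must be one of: ", paste(kinds, collapse = ", ")))
  if (length(object@wavelengths) != length(object@intensities))
    msg <- c(msg, "'wavelengths' and 'intensities' must have equal length")
  if (length(object@wavelengths) >= 2L && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "'wavelengths' must be strictly ascending")
  if (length(msg)) msg else TRUE
})

#' Constant delta-lambda synchronous spectrum
#'
#' A synchronous fluorescence trace: the EEM sampled along the diagonal
#' \code{em = ex + deltaLambda}, indexed by emission wavelength.
#'
#' @slot deltaLambda the constant offset in nm; > 0.
#' @seealso [synchronousSpectrum()], [firstDerivative()]
#' @export
setClass("SyncSpectrum",
  contains = "FluorSpectrum",
  representation(deltaLambda = "numeric")
)

setValidity("SyncSpectrum", function(object) {
  msg <- character()
  if (length(object@deltaLambda) != 1L || !is.finite(object@deltaLambda) ||
      object@deltaLambda <= 0)
    msg <- c(msg, "'deltaLambda' must be a single number > 0")
  if (!identical(object@axisKind, "synchronous-emission"))
    msg <- c(msg, "a SyncSpectrum must have axisKind 'synchronous-emission'")
  if (length(msg)) msg else TRUE
})

#' First-derivative spectrum
#'
#' The signed first derivative (the 1D trace) of a synchronous spectrum
#' with respect to wavelength, in AFU/nm. Positive amplitude where the
#' intensity rises with wavelength. \code{interval} is the (odd) point
#' count of the differentiation window; \code{meta} carries the source
#' synchronous spectrum's metadata plus the grid step, delta-lambda and
#' the edge width excluded from zero-crossing searches.
#'
#' @slot wavelengths nm axis (same as the source spectrum).
#' @slot amplitudes signed AFU/nm.
#' @slot interval odd integer window size in points.
#' @slot meta named list.
#' @seealso [firstDerivative()], [findZeroCrossings()], [amplitudeAt()]
#' @export
setClass("DerivSpectrum",
  representation(
    wavelengths = "numeric",
    amplitudes = "numeric",
    interval = "integer",
    meta = "list"
  )
)

setValidity("DerivSpectrum", function(object) {
  msg <- character()
  if (length(object@wavelengths) != length(object@amplitudes))
    msg <- c(msg, "'wavelengths' and 'amplitudes' must have equal length")
  if (length(object@interval) != 1L || object@interval < 3L ||
      object@interval %% 2L == 0L)
    msg <- c(msg, "'interval' must be a single odd integer >= 3")
  if (length(msg)) msg else TRUE
})

#' Univariate calibration curve
#'
#' Ordinary least-squares fit of signed first-derivative amplitude against
#' concentration for one analyte at one measurement wavelength.
#' \code{sigmaIntercept} is the standard deviation of the y-intercepts of
#' per-replicate refits (the sigma of the ICH LOD/LOQ formulas); it is
#' \code{NA} when fewer than two replicate curves are available.
#'
#' @slot analyte analyte name.
#' @slot wavelength measurement wavelength, nm.
#' @slot slope (AFU/nm) per (ug/mL).
#' @slot intercept AFU/nm.
#' @slot r,rSquared correlation coefficient and determination coefficient.
#' @slot sigmaIntercept SD of replicate-curve intercepts, or NA.
#' @slot rangeLow,rangeHigh validated concentration range, ug/mL.
#' @slot n number of calibration points.
#' @seealso [fitCalibration()], [predictConcentration()], [lodLoq()]
#' @export
setClass("CalibrationCurve",
  representation(
    analyte = "character",
    wavelength = "numeric",
    slope = "numeric",
    intercept = "numeric",
    r = "numeric",
    rSquared = "numeric",
    sigmaIntercept = "numeric",
    rangeLow = "numeric",
    rangeHigh = "numeric",
    n = "integer"
  )
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (object@n < 3L) msg <- c(msg, "a calibration needs >= 3 points")
  if (!is.na(object@rangeLow) && !is.na(object@rangeHigh) &&
      object@rangeLow >= object@rangeHigh)
    msg <- c(msg, "'rangeLow' must be below 'rangeHigh'")
  if (length(msg)) msg else TRUE
})

#' Two-method statistical comparison
#'
#' Pooled-variance two-sample t and variance-ratio F comparison of percent
#' recoveries from two methods, with two-tailed 95% critical values. The t
#' statistic is reported unsigned; F uses the larger/smaller convention so
#' \code{fStatistic >= 1}.
#'
#' @slot n1,n2 sample sizes.
#' @slot mean1,mean2 mean percent recovery per method.
#' @slot var1,var2 recovery variances.
#' @slot tStatistic,fStatistic the test statistics.
#' @slot dfT degrees of freedom of the t test (n1 + n2 - 2).
#' @slot dfF numerator and denominator F degrees of freedom.
#' @slot criticalT,criticalF tabulated values at the 95% confidence level.
#' @seealso [compareMethods()]
#' @export
setClass("MethodComparison",
  representation(
    n1 = "integer", n2 = "integer",
    mean1 = "numeric", mean2 = "numeric",
    var1 = "numeric", var2 = "numeric",
    tStatistic = "numeric", fStatistic = "numeric",
    dfT = "integer", dfF = "integer",
    criticalT = "numeric", criticalF = "numeric"
  )
)

setValidity("MethodComparison", function(object) {
  msg <- character()
  if (object@fStatistic < 1) msg <- c(msg, "'fStatistic' must be >= 1 (larger/smaller convention)")
  if (object@dfT != object@n1 + object@n2 - 2L)
    msg <- c(msg, "'dfT' must equal n1 + n2 - 2")
  if (length(object@dfF) != 2L) msg <- c(msg, "'dfF' must be (numerator, denominator)")
  if (length(msg)) msg else TRUE
})

#' Run configuration
#'
#' Bundles every tunable of the analysis pipeline: the synchronous scan
#' offset (default 80 nm), the derivative window (default 15 points,
#' Savitzky-Golay order 2), per-analyte measurement wavelengths (numeric nm
#' or \code{"auto"} for zero-crossing selection), calibration levels,
#' replicate count, the simulator's noise/background, the scan axes and
#' acceptance thresholds.
#'
#' @slot deltaLambda synchronous offset, nm; > 0.
#' @slot derivativeInterval odd window size in points, >= 3.
#' @slot derivativeMode \code{"savgol"} (default) or \code{"lagged"}
#'   (plain central difference over the same point gap).
#' @slot measurementWavelengths named list; each entry a wavelength in nm
#'   or the string \code{"auto"}.
#' @slot sensitivityFloor fraction of the analyte's max |1D| a wavelength
#'   must retain to be eligible for measurement.
#' @slot minFlank zero-crossing noise guard, AFU/nm.
#' @slot calibrationLevels named list of ug/mL vectors per analyte.
#' @slot replicates calibration replicate count.
#' @slot noise a \linkS4class{NoiseModel}.
#' @slot background flat excipient background, AFU.
#' @slot exGrid,emGrid scan axes, nm.
#' @slot seed master seed.
#' @slot rsdLimit,recoveryLow,recoveryHigh acceptance thresholds
#'   (percent RSD limit; recovery band bounds, percent).
#' @seealso [runConfig()], [loadConfig()]
#' @export
setClass("RunConfig",
  representation(
    deltaLambda = "numeric",
    derivativeInterval = "integer",
    derivativeMode = "character",
    measurementWavelengths = "list",
    sensitivityFloor = "numeric",
    minFlank = "numeric",
    calibrationLevels = "list",
    replicates = "integer",
    noise = "NoiseModel",
    background = "numeric",
    exGrid = "numeric",
    emGrid = "numeric",
    seed = "integer",
    rsdLimit = "numeric",
    recoveryLow = "numeric",
    recoveryHigh = "numeric"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@deltaLambda <= 0) msg <- c(msg, "'deltaLambda' must be > 0")
  if (object@derivativeInterval < 3L)
    msg <- c(msg, "'derivativeInterval' must be >= 3")
  if (object@derivativeInterval %% 2L == 0L)
    msg <- c(msg, "'derivativeInterval' must be odd: the derivative window needs a centre point")
  if (!object@derivativeMode %in% c("savgol", "lagged"))
    msg <- c(msg, "'derivativeMode' must be 'savgol' or 'lagged'")
  if (!is.null(.checkGrid(object@exGrid, "exGrid")))
    msg <- c(msg, .checkGrid(object@exGrid, "exGrid"))
  if (!is.null(.checkGrid(object@emGrid, "emGrid")))
    msg <- c(msg, .checkGrid(object@emGrid, "emGrid"))
  if (length(msg)) msg else TRUE
})

#' Validation report
#'
#' Per-analyte validation blocks (linearity, LOD/LOQ, accuracy, precision,
#' robustness) plus an optional two-method comparison, assembled by
#' [buildValidationReport()] and rendered by [renderReport()].
#'
#' @slot analytes named list; one complete block per analyte.
#' @slot comparison a \linkS4class{MethodComparison} or NULL.
#' @export
setClass("ValidationReport",
  representation(analytes = "list", comparison = "ANY")
)
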