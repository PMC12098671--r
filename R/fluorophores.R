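#' @include AllClasses.R utils.R
NULL

#' Construct a Gaussian-band fluorophore model
#'
#' @param name analyte name.
#' @param exMax,emMax excitation and emission band maxima, nm
#'   (\code{emMax > exMax}).
#' @param exWidth,emWidth Gaussian SD of the bands, nm; > 0.
#' @param brightness AFU per (ug/mL) at the band maxima; >= 0.
#' @return a \linkS4class{Fluorophore}.
#' @examples
#' asp <- fluorophore("ASP", exMax = 285, emMax = 405,
#'                    exWidth = 28, emWidth = 29.4, brightness = 100)
#' bandIntensity(asp, ex = 285, em = 405)
#' @export
fluorophore <- function(name, exMax, emMax, exWidth, emWidth, brightness) {
  new("Fluorophore", name = as.character(name),
      exMax = as.numeric(exMax), emMax = as.numeric(emMax),
      exWidth = as.numeric(exWidth), emWidth = as.numeric(emWidth),
      brightness = as.numeric(brightness))
}

#' Construct a noise model
#'
#' @param additiveSd additive Gaussian noise SD, AFU.
#' @param proportionalCv proportional Gaussian noise CV (fraction of the
#'   local noiseless intensity).
#' @return a \linkS4class{NoiseModel}.
#' @export
noiseModel <- function(additiveSd = 0, proportionalCv = 0) {
  new("NoiseModel", additiveSd = as.numeric(additiveSd),
      proportionalCv = as.numeric(proportionalCv))
}

#' Default instrument noise
#'
#' Package default repeatability noise, calibrated once (see the tuning
#' script under \code{tools/}) so that triplicate quantification of a
#' mid-range sample shows a percent RSD of the order of 1%, the
#' repeatability magnitude typical of a bench spectrofluorometer running
#' this assay.
#'
#' @return a \linkS4class{NoiseModel}.
#' @export
defaultNoise <- function() noiseModel(additiveSd = 0.1, proportionalCv = 0.002)

#' Unit band intensity of a fluorophore
#'
#' Separable Gaussian response: \code{brightness *
#' exp(-(ex - exMax)^2 / (2 exWidth^2)) * exp(-(em - emMax)^2 / (2 emWidth^2))},
#' i.e. the AFU per (ug/mL) the fluorophore contributes at an
#' excitation/emission wavelength pair. Vectorised over \code{ex}/\code{em}.
#'
#' @param model a \linkS4class{Fluorophore}.
#' @param ex,em excitation and emission wavelengths, nm.
#' @return AFU per (ug/mL); never negative.
#' @export
bandIntensity <- function(model, ex, em) {
  stopifnot(is(model, "Fluorophore"))
  if (any(!is.finite(ex)) || any(!is.finite(em)))
    dataError("wavelengths passed to bandIntensity() must be finite")
  model@brightness *
    exp(-(ex - model@exMax)^2 / (2 * model@exWidth^2)) *
    exp(-(em - model@emMax)^2 / (2 * model@emWidth^2))
}

#' Default aspirin-like and atorvastatin-like band models
#'
#' Two overlapped fluorophores emulating the co-formulated pair the package
#' is modelled on: an ASP-like analyte (excitation maximum 285 nm, emission
#' maximum 405 nm) and an ATO-like analyte (excitation 300 nm, emission
#' 364 nm). Band widths and relative brightness are package constants,
#' frozen from a one-off grid search (script under \code{tools/}) chosen so
#' that at the default 80 nm synchronous offset each pure analyte's
#' first-derivative trace has a zero crossing close to the other analyte's
#' literature measurement wavelength (384 nm for the ATO channel, 365 nm
#' for the ASP channel) and the two synchronous peaks are well separated.
#' The widths are a modelling stand-in, not a claim about the real spectra.
#'
#' @return named list with elements \code{ASP} and \code{ATO}.
#' @examples
#' m <- defaultModels()
#' m$ASP@emMax  # 405
#' m$ATO@exMax  # 300
#' @export
defaultModels <- function() {
  list(
    ASP = fluorophore("ASP", exMax = 285, emMax = 405,
                      exWidth = 28, emWidth = 29.4, brightness = 100),
    ATO = fluorophore("ATO", exMax = 300, emMax = 364,
                      exWidth = 60, emWidth = 17, brightness = 150)
  )
}

#' Closed-form synchronous peak position of a single Gaussian band
#'
#' For a separable Gaussian fluorophore scanned at constant offset
#' delta-lambda, the synchronous trace (on the emission axis) is itself a
#' Gaussian: the product of the excitation Gaussian evaluated at
#' \code{em - deltaLambda} and the emission Gaussian. Its peak sits at the
#' precision-weighted mean \code{((exMax + deltaLambda)/exWidth^2 +
#' emMax/emWidth^2) / (1/exWidth^2 + 1/emWidth^2)}. Used as the independent
#' oracle for the numerical synchronous slice.
#'
#' @param model a \linkS4class{Fluorophore}.
#' @param deltaLambda the scan offset, nm.
#' @return peak emission wavelength, nm.
#' @export
syncPeakTheory <- function(model, deltaLambda) {
  wx <- 1 / model@exWidth^2
  wm <- 1 / model@emWidth^2
  ((model@exMax + deltaLambda) * wx + model@emMax * wm) / (wx + wm)
}

setMethod("show", "Fluorophore", function(object) {
  cat(sprintf(
    "Fluorophore '%s': ex %g nm (SD %g), em %g nm (SD %g), brightness %g AFU/(ug/mL)\n",
    object@name, object@exMax, object@exWidth,
    object@emMax, object@emWidth, object@brightness))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: additive SD %g AFU, proportional CV %g\n",
              object@additiveSd, object@proportionalCv))
})
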