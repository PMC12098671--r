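#' Wavelength axis of a spectrum-like object
#'
#' @param object a \linkS4class{FluorSpectrum}, \linkS4class{DerivSpectrum}
#'   or \linkS4class{EEM}.
#' @return For 1-D objects, the numeric wavelength axis in nm. For an
#'   \code{EEM}, a list with elements \code{ex} and \code{em}.
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' Intensity values of a spectrum-like object
#'
#' @param object a \linkS4class{FluorSpectrum} or \linkS4class{EEM}.
#' @return Numeric vector (1-D spectra) or matrix indexed
#'   \code{[ex, em]} (EEM), in arbitrary fluorescence units (AFU).
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' Signed first-derivative amplitudes
#'
#' @param object a \linkS4class{DerivSpectrum}.
#' @return Numeric vector of signed amplitudes in AFU/nm.
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))

#' Constant wavelength offset of a synchronous scan
#'
#' @param object a \linkS4class{SyncSpectrum} or \linkS4class{RunConfig}.
#' @return The delta-lambda offset in nm.
#' @export
setGeneric("deltaLambda", function(object) standardGeneric("deltaLambda"))

#' Metadata attached to a spectroscopy object
#'
#' @param object a spectrum, EEM or derivative object.
#' @return A named list.
#' @export
setGeneric("spectrumMeta", function(object) standardGeneric("spectrumMeta"))
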