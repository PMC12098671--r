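#' @include fluorophores.R
NULL

#' Simulate an excitation-emission matrix
#'
#' Linear additive fluorescence: the noiseless intensity at each (ex, em)
#' grid cell is the concentration-weighted sum of the fluorophores' Gaussian
#' band responses plus a flat non-fluorescent background. Replicate noise
#' (additive + proportional Gaussian) is then applied cell-wise. Identical
#' inputs and seed give an identical EEM.
#'
#' @param models list of \linkS4class{Fluorophore} (may be empty).
#' @param concentrations numeric vector of ug/mL, one per model; must be
#'   non-negative.
#' @param exWavelengths,emWavelengths scan axes (see [wavelengthGrid()]);
#'   defaults cover 220-500 / 250-600 nm at 1 nm.
#' @param noise a \linkS4class{NoiseModel}.
#' @param background flat excipient background, AFU; >= 0.
#' @param seed RNG seed for the noise draw (required when noise is
#'   non-zero).
#' @return an \linkS4class{EEM} whose \code{meta} records concentrations,
#'   background, seed and noise settings.
#' @examples
#' m <- defaultModels()
#' eem <- simulateEEM(m, c(ASP = 6, ATO = 2))
#' dim(intensities(eem))
#' @export
simulateEEM <- function(models, concentrations,
                        exWavelengths = wavelengthGrid(220, 500, 1),
                        emWavelengths = wavelengthGrid(250, 600, 1),
                        noise = noiseModel(0, 0),
                        background = 0, seed = NULL) {
  if (is(models, "Fluorophore")) models <- list(models)
  stopifnot(length(models) == length(concentrations))
  if (background < 0) dataError("background must be >= 0")
  nms <- names(concentrations)
  if (is.null(nms)) nms <- vapply(models, function(m) m@name, character(1))
  bad <- which(!is.finite(concentrations) | concentrations < 0)
  if (length(bad))
    dataError("negative or non-finite concentration for analyte '%s'",
              nms[bad[1]])
  names(concentrations) <- nms

  clean <- matrix(background,
                  nrow = length(exWavelengths), ncol = length(emWavelengths))
  for (i in seq_along(models)) {
    m <- models[[i]]
    gx <- exp(-(exWavelengths - m@exMax)^2 / (2 * m@exWidth^2))
    gm <- exp(-(emWavelengths - m@emMax)^2 / (2 * m@emWidth^2))
    clean <- clean + concentrations[i] * m@brightness * outer(gx, gm)
  }

  intens <- clean
  noisy <- noise@additiveSd > 0 || noise@proportionalCv > 0
  if (noisy) {
    if (is.null(seed))
      dataError("a seed is required when simulating with non-zero noise")
    n <- length(clean)
    intens <- withSeed(seed, {
      clean + stats::rnorm(n, 0, noise@additiveSd) +
        clean * noise@proportionalCv * stats::rnorm(n)
    })
  }

  new("EEM", exWavelengths = exWavelengths, emWavelengths = emWavelengths,
      intensities = intens,
      meta = list(concentrations = concentrations, background = background,
                  seed = if (noisy) as.integer(seed) else NA_integer_,
                  additiveSd = noise@additiveSd,
                  proportionalCv = noise@proportionalCv))
}

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "EEM", function(object)
  list(ex = object@exWavelengths, em = object@emWavelengths))

#' @rdname intensities
#' @export
setMethod("intensities", "EEM", function(object) object@intensities)

#' @rdname spectrumMeta
#' @export
setMethod("spectrumMeta", "EEM", function(object) object@meta)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "FluorSpectrum", function(object) object@wavelengths)

#' @rdname intensities
#' @export
setMethod("intensities", "FluorSpectrum", function(object) object@intensities)

#' @rdname spectrumMeta
#' @export
setMethod("spectrumMeta", "FluorSpectrum", function(object) object@meta)

#' @rdname deltaLambda
#' @export
setMethod("deltaLambda", "SyncSpectrum", function(object) object@deltaLambda)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "DerivSpectrum", function(object) object@wavelengths)

#' @rdname amplitudes
#' @export
setMethod("amplitudes", "DerivSpectrum", function(object) object@amplitudes)

#' @rdname spectrumMeta
#' @export
setMethod("spectrumMeta", "DerivSpectrum", function(object) object@meta)

setMethod("show", "EEM", function(object) {
  cc <- object@meta$concentrations
  cat(sprintf("EEM: %d ex x %d em points, ex %s, em %s\n",
              length(object@exWavelengths), length(object@emWavelengths),
              fmtRange(min(object@exWavelengths), max(object@exWavelengths)),
              fmtRange(min(object@emWavelengths), max(object@emWavelengths))))
  if (length(cc))
    cat("  sample:", paste(sprintf("%s %g ug/mL", names(cc), cc),
                           collapse = ", "), "\n")
})

setMethod("show", "FluorSpectrum", function(object) {
  cat(sprintf("%s spectrum: %d points, %s\n", object@axisKind,
              length(object@wavelengths),
              fmtRange(min(object@wavelengths), max(object@wavelengths))))
})

setMethod("show", "SyncSpectrum", function(object) {
  cat(sprintf(
    "Synchronous spectrum (delta-lambda %g nm): %d points, %s\n",
    object@deltaLambda, length(object@wavelengths),
    fmtRange(min(object@wavelengths), max(object@wavelengths))))
})

setMethod("show", "DerivSpectrum", function(object) {
  cat(sprintf(
    "First-derivative spectrum (%d-point window): %d points, %s\n",
    object@interval, length(object@wavelengths),
    fmtRange(min(object@wavelengths), max(object@wavelengths))))
})
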