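#' @include config.R
NULL

#' Extract a constant delta-lambda synchronous spectrum
#'
#' Slices the EEM along the diagonal \code{ex = em - deltaLambda} and
#' reports the trace on the emission axis. Emission points whose paired
#' excitation wavelength falls outside the excitation grid are dropped;
#' off-grid excitation wavelengths are resolved by linear interpolation
#' along the excitation axis (the emission coordinate is always on-grid,
#' so this is the bilinear rule restricted to one axis).
#'
#' @param eem an \linkS4class{EEM}.
#' @param deltaLambda scan offset, nm; must leave at least 20 points of
#'   overlap between the shifted emission axis and the excitation grid.
#' @return a \linkS4class{SyncSpectrum}.
#' @examples
#' eem <- simulateEEM(defaultModels(), c(ASP = 6, ATO = 2))
#' s <- synchronousSpectrum(eem, 80)
#' @export
synchronousSpectrum <- function(eem, deltaLambda) {
  stopifnot(is(eem, "EEM"))
  if (!is.finite(deltaLambda) || deltaLambda <= 0)
    dataError("'deltaLambda' must be a single positive offset in nm")
  ex <- eem@exWavelengths
  em <- eem@emWavelengths
  target <- em - deltaLambda
  keep <- target >= ex[1] & target <= ex[length(ex)]
  if (sum(keep) < 20L) {
    lo <- ex[1] + deltaLambda
    hi <- ex[length(ex)] + deltaLambda
    dataError(paste0("delta-lambda %g nm leaves %d overlapping points ",
                     "(>= 20 required); usable emission range is %s"),
              deltaLambda, sum(keep), fmtRange(max(lo, em[1]), min(hi, em[length(em)])))
  }
  emKeep <- em[keep]
  idx <- which(keep)
  step <- gridStep(ex)
  pos <- (emKeep - deltaLambda - ex[1]) / step
  i <- pmin(pmax(floor(pos + 1e-9), 0), length(ex) - 2)
  f <- pos - i
  # guard exact upper edge
  f[f < 0] <- 0
  lowRow <- eem@intensities[cbind(i + 1, idx)]
  highRow <- eem@intensities[cbind(i + 2, idx)]
  vals <- lowRow * (1 - f) + highRow * f
  meta <- eem@meta
  meta$units <- "AFU"
  new("SyncSpectrum", axisKind = "synchronous-emission",
      wavelengths = emKeep, intensities = as.numeric(vals),
      deltaLambda = as.numeric(deltaLambda), meta = meta)
}
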