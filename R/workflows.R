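#' @include scan.R
NULL

#' Calibrate both analyte channels from pure panels
#'
#' Runs the full channel setup for every analyte in \code{purePanels}:
#' synchronous slice at the config's delta-lambda, Savitzky-Golay first
#' derivative, measurement-wavelength selection (the config may pin a
#' wavelength per analyte; \code{"auto"} applies the zero-crossing rule),
#' amplitude measurement per panel EEM and an OLS calibration with
#' per-replicate intercept refits.
#'
#' @param purePanels named list of per-analyte lists of \linkS4class{EEM}
#'   (e.g. from [calibrationPanel()]).
#' @param config a \linkS4class{RunConfig}.
#' @return named list of \linkS4class{CalibrationCurve}.
#' @export
calibrateChannels <- function(purePanels, config = runConfig()) {
  out <- list()
  for (analyte in names(purePanels)) {
    mw <- config@measurementWavelengths[[analyte]]
    fixed <- if (!is.null(mw) && !identical(mw, "auto")) as.numeric(mw) else NULL
    setup <- channelSetup(analyte, purePanels, config@deltaLambda,
                          config@derivativeInterval, config@derivativeMode,
                          config@sensitivityFloor, fixedWavelength = fixed)
    reps <- vapply(purePanels[[analyte]], function(e) {
      s <- e@meta$sample
      if (is.null(s$replicate)) 1L else as.integer(s$replicate)
    }, integer(1))
    out[[analyte]] <- fitCalibration(setup$levels, setup$amplitudes,
                                     replicates = reps, analyte = analyte,
                                     wavelength = setup$wavelength)
  }
  out
}

# one EEM -> per-analyte found concentrations (shared pipeline core)
quantifyEEM <- function(eem, curves, config) {
  sync <- synchronousSpectrum(eem, config@deltaLambda)
  deriv <- firstDerivative(sync, config@derivativeInterval, config@derivativeMode)
  rows <- lapply(names(curves), function(a) {
    cu <- curves[[a]]
    amp <- amplitudeAt(deriv, cu@wavelength)
    found <- predictConcentration(cu, amp)
    data.frame(analyte = a, wavelength = cu@wavelength, amplitude = amp,
               found = as.numeric(found),
               out_of_range = attr(found, "outOfRange"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantify a binary mixture
#'
#' Full pipeline per analyte: synchronous slice, first derivative,
#' amplitude at the analyte's measurement wavelength, inverse prediction.
#' When the EEM metadata (or \code{truth}) carries the true
#' concentrations, percent recoveries are attached.
#'
#' @param eem an \linkS4class{EEM}.
#' @param curves named list of \linkS4class{CalibrationCurve}; every
#'   requested analyte must have one.
#' @param config a \linkS4class{RunConfig} (must match the delta-lambda
#'   and interval the curves were built with).
#' @param analytes analytes to report; default all calibrated.
#' @param truth optional named ug/mL vector overriding the EEM metadata.
#' @return data.frame with columns \code{analyte, wavelength, amplitude,
#'   found, out_of_range} and, when truth is known, \code{added,
#'   percent_recovery}.
#' @export
analyzeMixture <- function(eem, curves, config = runConfig(),
                           analytes = names(curves), truth = NULL) {
  missing <- setdiff(analytes, names(curves))
  if (length(missing))
    dataError("no calibration curve for analyte(s): %s",
              paste(missing, collapse = ", "))
  res <- quantifyEEM(eem, curves[analytes], config)
  if (is.null(truth)) truth <- eem@meta$concentrations
  if (!is.null(truth)) {
    res$added <- as.numeric(truth[res$analyte])
    res$percent_recovery <- ifelse(res$added > 0,
                                   100 * res$found / res$added, NA_real_)
  }
  res
}

#' Standard-addition accounting
#'
#' Subtraction accounting: the recovery of a spike is computed from the
#' concentration found before the spike, the amount added, and the total
#' found after the spike: \code{pure_found = total_found - base_found},
#' \code{percent_recovery = 100 * pure_found / added}. A negative pure
#' found is kept but flagged.
#'
#' @param baseFound concentration found in the unspiked preparation, ug/mL.
#' @param added spiked pure analyte, ug/mL; > 0.
#' @param totalFound concentration found after spiking, ug/mL; >= 0.
#' @return data.frame with columns \code{base_found, added, total_found,
#'   pure_found, percent_recovery, flagged}. Vectorised.
#' @examples
#' standardAddition(75.21, 7.5, 82.847)  # pure found 7.637, 101.83%
#' @export
standardAddition <- function(baseFound, added, totalFound) {
  if (any(added <= 0)) dataError("'added' must be > 0")
  if (any(totalFound < 0)) dataError("'totalFound' must be >= 0")
  pure <- totalFound - baseFound
  data.frame(base_found = baseFound, added = added, total_found = totalFound,
             pure_found = pure, percent_recovery = 100 * pure / added,
             flagged = pure < 0)
}

#' Tablet assay against label claim
#'
#' Quantifies a dilution series of a tablet extract and reports, per
#' analyte, the mean percent recovery against the nominal (label-claim
#' derived) concentrations and the sample percent RSD over the
#' determinations. The workflow expects the usual five dilution levels; a
#' different count is allowed with a warning.
#'
#' @param eems list of \linkS4class{EEM}, one per dilution level.
#' @param nominal data.frame/matrix of nominal ug/mL, rows = levels,
#'   columns named by analyte; all > 0.
#' @param curves named list of \linkS4class{CalibrationCurve}.
#' @param config a \linkS4class{RunConfig}.
#' @return list with \code{perLevel} (data.frame of level, analyte, found,
#'   nominal, percent_recovery) and \code{summary} (data.frame of analyte,
#'   mean_recovery, rsd, n).
#' @export
tabletAssay <- function(eems, nominal, curves, config = runConfig()) {
  nominal <- as.data.frame(nominal)
  if (length(eems) != nrow(nominal))
    dataError("one nominal row per dilution level is required")
  if (any(as.matrix(nominal) <= 0))
    dataError("nominal (label-claim) concentrations must be > 0")
  if (length(eems) != 5L)
    warning(sprintf("tablet assay usually uses 5 dilution levels (got %d); computing anyway",
                    length(eems)))
  rows <- lapply(seq_along(eems), function(i) {
    q <- quantifyEEM(eems[[i]], curves[names(nominal)], config)
    q$level <- i
    q$nominal <- as.numeric(nominal[i, q$analyte])
    q$percent_recovery <- 100 * q$found / q$nominal
    q
  })
  perLevel <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(names(nominal), function(a) {
    r <- perLevel$percent_recovery[perLevel$analyte == a]
    data.frame(analyte = a, mean_recovery = mean(r),
               rsd = 100 * stats::sd(r) / mean(r), n = length(r))
  }))
  list(perLevel = perLevel, summary = summary)
}
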