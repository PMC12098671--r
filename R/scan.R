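#' @include calibration.R
NULL

panelDerivatives <- function(panel, deltaLambda, interval, mode = "savgol") {
  lapply(panel, function(eem)
    firstDerivative(synchronousSpectrum(eem, deltaLambda), interval, mode))
}

panelConcentration <- function(eem, analyte) {
  cc <- eem@meta$concentrations
  if (is.null(cc) || !analyte %in% names(cc))
    dataError("EEM metadata carries no concentration for analyte '%s'", analyte)
  unname(cc[analyte])
}

# measurement wavelength + slope for one analyte at one delta-lambda;
# shared by the scan scorer and the calibration workflow
channelSetup <- function(analyte, purePanels, deltaLambda, interval,
                         mode = "savgol", sensitivityFloor = 0.2,
                         fixedWavelength = NULL) {
  ownDerivs <- panelDerivatives(purePanels[[analyte]], deltaLambda, interval, mode)
  others <- setdiff(names(purePanels), analyte)
  interfDerivs <- unlist(lapply(others, function(a)
    panelDerivatives(purePanels[[a]], deltaLambda, interval, mode)),
    recursive = FALSE)
  levels <- vapply(purePanels[[analyte]], panelConcentration, numeric(1), analyte = analyte)
  reference <- ownDerivs[[which.max(levels)]]
  lambda <- if (!is.null(fixedWavelength)) fixedWavelength
  else selectMeasurementWavelength(interfDerivs, reference,
                                   sensitivityFloor = sensitivityFloor)
  amps <- vapply(ownDerivs, amplitudeAt, numeric(1), wavelength = lambda)
  slope <- stats::coef(stats::lm(amps ~ levels))[[2]]
  list(wavelength = lambda, slope = slope, levels = levels,
       amplitudes = amps, derivs = ownDerivs)
}

#' Score candidate delta-lambda offsets
#'
#' Evaluates each candidate synchronous offset on pure-analyte panels: the
#' per-analyte measurement wavelength is auto-selected by the zero-crossing
#' rule, the calibration sensitivity |slope| is estimated at it, and the
#' candidate is scored as \code{|slope_A| * |slope_B| * min(separation,
#' 50 nm)}, rewarding offsets that keep both channels sensitive and the two
#' measurement wavelengths apart ("two well-defined peaks"). Candidates
#' with insufficient grid overlap or unresolvable channels score
#' \code{-Inf} and are flagged; spectrally identical analytes give zero
#' separation, zero score and an "unresolvable" flag. Ties take the
#' smallest offset.
#'
#' @param purePanels named list (one entry per analyte) of lists of
#'   \linkS4class{EEM} of the pure analyte at >= 2 concentrations.
#' @param candidates offsets to score, nm; non-empty.
#' @param config a \linkS4class{RunConfig} (derivative settings and
#'   sensitivity floor are taken from it).
#' @return list with \code{best} (nm) and \code{table} (data.frame with
#'   columns \code{delta_lambda_nm, score, lambda_A, lambda_B, slope_A,
#'   slope_B, note}).
#' @export
scanDeltaLambda <- function(purePanels, candidates, config = runConfig()) {
  if (!length(candidates)) dataError("'candidates' must not be empty")
  if (length(purePanels) != 2L)
    dataError("the delta-lambda scan expects exactly two pure-analyte panels")
  for (a in names(purePanels)) {
    lv <- vapply(purePanels[[a]], panelConcentration, numeric(1), analyte = a)
    if (length(unique(lv)) < 2L)
      dataError("panel for '%s' needs >= 2 distinct concentrations", a)
  }
  candidates <- sort(candidates)
  nm <- names(purePanels)
  rows <- lapply(candidates, function(dl) {
    res <- tryCatch({
      a <- channelSetup(nm[1], purePanels, dl, config@derivativeInterval,
                        config@derivativeMode, config@sensitivityFloor)
      b <- channelSetup(nm[2], purePanels, dl, config@derivativeInterval,
                        config@derivativeMode, config@sensitivityFloor)
      sep <- abs(a$wavelength - b$wavelength)
      score <- abs(a$slope) * abs(b$slope) * min(sep, 50)
      note <- if (sep == 0) "unresolvable" else ""
      data.frame(delta_lambda_nm = dl, score = score,
                 lambda_A = a$wavelength, lambda_B = b$wavelength,
                 slope_A = a$slope, slope_B = b$slope, note = note)
    }, syncfluorError = function(e) {
      data.frame(delta_lambda_nm = dl, score = -Inf,
                 lambda_A = NA_real_, lambda_B = NA_real_,
                 slope_A = NA_real_, slope_B = NA_real_,
                 note = conditionMessage(e))
    })
    res
  })
  table <- do.call(rbind, rows)
  if (all(!is.finite(table$score) & table$score < 0))
    numericError("no candidate delta-lambda produced a usable channel pair")
  list(best = table$delta_lambda_nm[which.max(table$score)], table = table)
}
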