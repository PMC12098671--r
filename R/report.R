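#' @include validation.R
NULL

.reportFields <- c("wavelength", "linearity_range", "r_squared", "intercept",
                   "slope", "lod", "loq", "accuracy", "repeatability",
                   "intermediate_precision", "robustness")

#' Assemble a validation report
#'
#' @param analytes named list; each element a list with entries
#'   \code{wavelength} (nm), \code{rangeLow}/\code{rangeHigh} (ug/mL),
#'   \code{rSquared}, \code{intercept}, \code{slope}, \code{lod},
#'   \code{loq}, \code{accuracy} (mean percent recovery),
#'   \code{repeatability} and \code{intermediatePrecision} (percent RSD)
#'   and \code{robustness} (named numeric of percent RSD per axis).
#' @param comparison optional \linkS4class{MethodComparison}.
#' @return a \linkS4class{ValidationReport}.
#' @seealso [renderReport()]
#' @export
buildValidationReport <- function(analytes, comparison = NULL) {
  need <- c("wavelength", "rangeLow", "rangeHigh", "rSquared", "intercept",
            "slope", "lod", "loq", "accuracy", "repeatability",
            "intermediatePrecision", "robustness")
  for (a in names(analytes)) {
    miss <- setdiff(need, names(analytes[[a]]))
    if (length(miss))
      dataError("validation block for '%s' is missing: %s", a,
                paste(miss, collapse = ", "))
  }
  new("ValidationReport", analytes = analytes, comparison = comparison)
}

reportTable <- function(report) {
  rows <- list()
  for (a in names(report@analytes)) {
    b <- report@analytes[[a]]
    add <- function(param, value) {
      rows[[length(rows) + 1L]] <<- data.frame(
        analyte = a, parameter = param, value = value)
    }
    add("wavelength", b$wavelength)
    add("linearity_range_low", b$rangeLow)
    add("linearity_range_high", b$rangeHigh)
    add("r_squared", b$rSquared)
    add("intercept", b$intercept)
    add("slope", b$slope)
    add("lod", b$lod)
    add("loq", b$loq)
    add("accuracy", b$accuracy)
    add("repeatability", b$repeatability)
    add("intermediate_precision", b$intermediatePrecision)
    for (axis in names(b$robustness))
      add(paste0("robustness_", axis), b$robustness[[axis]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a validation report to CSV and text
#'
#' Writes a tidy CSV (\code{analyte,parameter,value}) covering the full
#' validation row set (measurement wavelength, linearity range, r2,
#' intercept, slope, LOD, LOQ, accuracy, repeatability, intermediate
#' precision, robustness) plus a human-readable text rendering at
#' \code{<path>.txt}. If a block's LOQ/LOD ratio deviates from the 10/3.3
#' the defining formulas force, a consistency warning is embedded in the
#' text output.
#'
#' @param report a \linkS4class{ValidationReport}.
#' @param path output CSV path.
#' @return the CSV path, invisibly.
#' @export
renderReport <- function(report, path) {
  stopifnot(is(report, "ValidationReport"))
  tab <- reportTable(report)
  con <- file(path, "w")
  writeHeader(con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  close(con)

  txt <- c(sprintf("Validation report (syncfluor %s)", pkgVersionString()), "")
  for (a in names(report@analytes)) {
    b <- report@analytes[[a]]
    txt <- c(txt, sprintf("== %s ==", a),
             sprintf("  wavelength            %.2f nm", b$wavelength),
             sprintf("  linearity_range       %g-%g ug/mL", b$rangeLow, b$rangeHigh),
             sprintf("  r_squared             %.4f", b$rSquared),
             sprintf("  intercept             %.4g", b$intercept),
             sprintf("  slope                 %.4g", b$slope),
             sprintf("  lod                   %.4g ug/mL", b$lod),
             sprintf("  loq                   %.4g ug/mL", b$loq),
             sprintf("  accuracy              %.2f %%R", b$accuracy),
             sprintf("  repeatability         %.3f %%RSD", b$repeatability),
             sprintf("  intermediate_precision %.3f %%RSD", b$intermediatePrecision))
    for (axis in names(b$robustness))
      txt <- c(txt, sprintf("  robustness_%-10s %.3f %%RSD", axis,
                            b$robustness[[axis]]))
    ratio <- b$loq / b$lod
    if (b$lod > 0 && abs(ratio - 10 / 3.3) > 1e-6)
      txt <- c(txt, sprintf(
        "  WARNING: LOQ/LOD ratio %.4f differs from the 10/3.3 = %.4f the formulas force",
        ratio, 10 / 3.3))
    txt <- c(txt, "")
  }
  if (!is.null(report@comparison)) {
    cmp <- report@comparison
    txt <- c(txt, "== method comparison ==",
             sprintf("  t = %.3f (critical %.3f, df %d)", cmp@tStatistic,
                     cmp@criticalT, cmp@dfT),
             sprintf("  F = %.3f (critical %.3f, df %d,%d)", cmp@fStatistic,
                     cmp@criticalF, cmp@dfF[1], cmp@dfF[2]))
  }
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d analyte(s)%s\n",
              length(object@analytes),
              if (is.null(object@comparison)) "" else " + method comparison"))
  for (a in names(object@analytes)) {
    b <- object@analytes[[a]]
    cat(sprintf("  %s: r2 %.4f, LOD %.3g, LOQ %.3g, accuracy %.2f%%\n",
                a, b$rSquared, b$lod, b$loq, b$accuracy))
  }
})
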