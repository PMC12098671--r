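#' @include report.R
NULL

#' Write / read calibration curves as CSV
#'
#' @param curves named list of \linkS4class{CalibrationCurve}.
#' @param path CSV file.
#' @return the path, or the named curve list for the reader.
#' @export
writeCalibrationCsv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cu) data.frame(
    analyte = cu@analyte, wavelength = cu@wavelength, slope = cu@slope,
    intercept = cu@intercept, r = cu@r, r_squared = cu@rSquared,
    sigma_intercept = cu@sigmaIntercept, range_low = cu@rangeLow,
    range_high = cu@rangeHigh, n = cu@n)))
  con <- file(path, "w")
  on.exit(close(con))
  writeHeader(con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCalibrationCsv
#' @export
readCalibrationCsv <- function(path) {
  if (!file.exists(path)) dataError("calibration file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("analyte", "wavelength", "slope", "intercept", "r", "r_squared",
            "sigma_intercept", "range_low", "range_high", "n")
  miss <- setdiff(need, names(df))
  if (length(miss))
    dataError("'%s' is missing calibration column(s): %s", path,
              paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    new("CalibrationCurve", analyte = df$analyte[i],
        wavelength = df$wavelength[i], slope = df$slope[i],
        intercept = df$intercept[i], r = df$r[i], rSquared = df$r_squared[i],
        sigmaIntercept = df$sigma_intercept[i], rangeLow = df$range_low[i],
        rangeHigh = df$range_high[i], n = as.integer(df$n[i]))
  })
  stats::setNames(out, df$analyte)
}

refFile <- function(name) {
  path <- system.file("extdata", name, package = "syncfluor")
  if (!nzchar(path)) dataError("reference dataset '%s' not installed", name)
  path
}

#' Published reference results bundled with the package
#'
#' Reference validation results for the co-formulated ATO/ASP assay the
#' simulator is modelled on, shipped as plain CSV under
#' \code{inst/extdata}: the laboratory-mixture selectivity study
#' (\code{refLabMixtures}), the standard-addition study
#' (\code{refStandardAddition}), and the reported-method comparison
#' summaries (\code{refMethodComparison}). Used to exercise the summary
#' arithmetic (recovery means, percent RSD, t/F) on real reported numbers.
#'
#' @return data.frame of the respective study.
#' @export
refLabMixtures <- function() {
  utils::read.csv(refFile("lab-mixtures.csv"), comment.char = "#")
}

#' @rdname refLabMixtures
#' @export
refStandardAddition <- function() {
  utils::read.csv(refFile("standard-addition.csv"), comment.char = "#")
}

#' @rdname refLabMixtures
#' @export
refMethodComparison <- function() {
  utils::read.csv(refFile("method-comparison.csv"), comment.char = "#")
}

demoStandardAddition <- function(curves, config, models, seed,
                                 base = c(ATO = 2, ASP = 7.5),
                                 spikes = c(0.5, 1, 1.5, 2)) {
  rows <- list()
  for (a in names(base)) {
    conc0 <- stats::setNames(numeric(length(models)), names(models))
    conc0[names(base)] <- base
    eem0 <- simulateEEM(models, conc0, config@exGrid, config@emGrid,
                        noise = config@noise, background = config@background,
                        seed = childSeed(seed, 500L))
    baseFound <- quantifyEEM(eem0, curves[a], config)$found
    for (i in seq_along(spikes)) {
      conc <- conc0
      conc[a] <- conc[a] + spikes[i]
      eem <- simulateEEM(models, conc, config@exGrid, config@emGrid,
                         noise = config@noise, background = config@background,
                         seed = childSeed(seed, 500L + 10L * match(a, names(base)) + i))
      totalFound <- quantifyEEM(eem, curves[a], config)$found
      rec <- standardAddition(baseFound, spikes[i], totalFound)
      rec$analyte <- a
      rows[[length(rows) + 1L]] <- rec
    }
  }
  do.call(rbind, rows)
}

demoAssay <- function(curves, config, models, seed,
                      atoLevels = c(0.8, 1.2, 1.6, 2, 2.4)) {
  nominal <- data.frame(ATO = atoLevels, ASP = 3.75 * atoLevels)
  eems <- lapply(seq_len(nrow(nominal)), function(i) {
    conc <- stats::setNames(numeric(length(models)), names(models))
    conc[names(nominal)] <- as.numeric(nominal[i, ])
    simulateEEM(models, conc, config@exGrid, config@emGrid,
                noise = config@noise, background = config@background,
                seed = childSeed(seed, 600L + i))
  })
  tabletAssay(eems, nominal, curves, config)
}

#' Run the full synthetic demonstration
#'
#' Executes the whole pipeline end to end with simulated data and writes
#' every result under \code{outDir}: pure-analyte panels and sample
#' sheets, the delta-lambda scan (20-120 nm), both calibrations, the
#' fixed-ratio laboratory-mixture recoveries, a standard-addition study,
#' a five-level tablet assay with a two-method comparison against the
#' bundled reference summaries, and the rendered validation report. The
#' run is deterministic given the master seed; a JSON manifest lists the
#' artifacts, seeds and configuration.
#'
#' @param seed master seed.
#' @param outDir writable output directory (created if needed).
#' @param config a \linkS4class{RunConfig}.
#' @param models simulator band models.
#' @return the manifest, invisibly (a list; also written as
#'   \code{manifest.json}).
#' @export
runDemo <- function(seed = 42, outDir = tempfile("syncfluor-demo-"),
                    config = runConfig(seed = seed),
                    models = defaultModels()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outDir, 2) != 0) dataError("'%s' is not writable", outDir)
  artifacts <- list()
  stage <- "init"
  outPath <- function(name) file.path(outDir, name)
  record <- function(stageName, ...) {
    files <- c(...)
    artifacts[[stageName]] <<- c(artifacts[[stageName]], files)
    files
  }
  tryCatch({
    stage <- "simulate"
    scanLevels <- function(lv) lv[unique(round(seq(1, length(lv), length.out = 3)))]
    scanPanels <- lapply(stats::setNames(names(models), names(models)),
      function(a) calibrationPanel(
        a, levels = scanLevels(config@calibrationLevels[[a]]),
        replicates = 1, noise = noiseModel(0, 0), seed = childSeed(seed, 100L),
        models = models, background = config@background,
        exWavelengths = config@exGrid, emWavelengths = config@emGrid))
    sheet <- panelSheet(scanPanels[[1]])
    writeSampleSheet(sheet, outPath("scan-panel-sheet.csv"))
    ex <- scanPanels[[1]][[1]]
    writeEEMCsv(ex, outPath("example-eem.csv"))
    writeSpectrumCsv(synchronousSpectrum(ex, config@deltaLambda),
                     outPath("example-sync-spectrum.csv"))
    record("simulate", outPath("scan-panel-sheet.csv"),
           outPath("example-eem.csv"), outPath("example-sync-spectrum.csv"))

    stage <- "scan"
    scan <- scanDeltaLambda(scanPanels, seq(20, 120, by = 10), config)
    con <- file(outPath("delta-lambda-scan.csv"), "w")
    writeHeader(con)
    utils::write.csv(scan$table, con, row.names = FALSE, quote = FALSE)
    close(con)
    record("scan", outPath("delta-lambda-scan.csv"))

    stage <- "calibrate"
    calPanels <- lapply(stats::setNames(names(models), names(models)),
      function(a) calibrationPanel(
        a, levels = config@calibrationLevels[[a]],
        replicates = config@replicates, noise = config@noise,
        seed = childSeed(seed, 200L + match(a, names(models))),
        models = models, background = config@background,
        exWavelengths = config@exGrid, emWavelengths = config@emGrid))
    curves <- calibrateChannels(calPanels, config)
    writeCalibrationCsv(curves, outPath("calibration.csv"))
    record("calibrate", outPath("calibration.csv"))

    stage <- "mixtures"
    mix <- mixturePanel(noise = config@noise, seed = childSeed(seed, 300L),
                        models = models, background = config@background,
                        exWavelengths = config@exGrid,
                        emWavelengths = config@emGrid)
    mixRows <- do.call(rbind, lapply(mix, analyzeMixture, curves = curves,
                                     config = config))
    con <- file(outPath("mixture-recoveries.csv"), "w")
    writeHeader(con)
    utils::write.csv(mixRows, con, row.names = FALSE, quote = FALSE)
    close(con)
    record("mixtures", outPath("mixture-recoveries.csv"))

    stage <- "standard_addition"
    sa <- demoStandardAddition(curves, config, models, seed)
    con <- file(outPath("standard-addition.csv"), "w")
    writeHeader(con)
    utils::write.csv(sa, con, row.names = FALSE, quote = FALSE)
    close(con)
    record("standard_addition", outPath("standard-addition.csv"))

    stage <- "validate"
    acc <- accuracyStudy(curves, config, models = models,
                         seed = childSeed(seed, 400L))
    repe <- precisionStudy(curves, config, days = 1, models = models,
                           seed = childSeed(seed, 410L))
    inter <- precisionStudy(curves, config, days = 3, replicates = 1,
                            models = models, seed = childSeed(seed, 420L))
    rob <- robustnessSweep(config, curves, models = models)
    assay <- demoAssay(curves, config, models, childSeed(seed, 430L))
    ref <- refMethodComparison()
    blocks <- lapply(stats::setNames(names(curves), names(curves)), function(a) {
      cu <- curves[[a]]
      lim <- lodLoq(cu)
      list(wavelength = cu@wavelength, rangeLow = cu@rangeLow,
           rangeHigh = cu@rangeHigh, rSquared = cu@rSquared,
           intercept = cu@intercept, slope = cu@slope,
           lod = lim[["lod"]], loq = lim[["loq"]],
           accuracy = acc$summary$mean_recovery[acc$summary$analyte == a],
           repeatability = repe$summary$percent_rsd[repe$summary$analyte == a],
           intermediatePrecision = inter$summary$percent_rsd[inter$summary$analyte == a],
           robustness = stats::setNames(
             rob$percent_rsd[rob$analyte == a],
             rob$axis[rob$analyte == a]))
    })
    cmpAnalyte <- names(curves)[1]
    refRow <- ref[ref$analyte == cmpAnalyte & ref$method == "reported", ]
    recoveries <- assay$perLevel$percent_recovery[
      assay$perLevel$analyte == cmpAnalyte]
    comparison <- compareMethods(recoveries,
                                 n2 = refRow$n, mean2 = refRow$mean_recovery,
                                 var2 = refRow$variance)
    report <- buildValidationReport(blocks, comparison)
    renderReport(report, outPath("validation-report.csv"))
    record("validate", outPath("validation-report.csv"),
           outPath("validation-report.csv.txt"))

    manifest <- list(
      package = "syncfluor", version = pkgVersionString(),
      seed = as.integer(seed),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = list(delta_lambda = config@deltaLambda,
                    derivative_interval = config@derivativeInterval,
                    derivative_mode = config@derivativeMode,
                    additive_sd = config@noise@additiveSd,
                    proportional_cv = config@noise@proportionalCv,
                    background = config@background),
      best_delta_lambda = scan$best,
      measurement_wavelengths = lapply(curves, function(cu) cu@wavelength),
      artifacts = artifacts)
    jsonlite::write_json(manifest, outPath("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    missingFiles <- unlist(artifacts)[!file.exists(unlist(artifacts))]
    if (length(missingFiles))
      numericError("demo finished but artifacts are missing: %s",
                   paste(missingFiles, collapse = ", "))
    invisible(manifest)
  }, syncfluorError = function(e) {
    jsonlite::write_json(
      list(failed_stage = stage, error = conditionMessage(e),
           artifacts = artifacts),
      outPath("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    stop(errorCondition(
      sprintf("demo failed at stage '%s': %s", stage, conditionMessage(e)),
      class = class(e)))
  })
}
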