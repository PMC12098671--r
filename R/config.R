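#' @include io.R
NULL

#' Construct a run configuration
#'
#' All arguments default to the package's standard operating point: a
#' synchronous offset of 80 nm, a 15-point Savitzky-Golay derivative
#' window, automatic (zero-crossing) measurement-wavelength selection,
#' six calibration levels spanning the validated ranges (ATO 0.4-6,
#' ASP 1-10 ug/mL) in triplicate, the default noise model, and the
#' standard acceptance thresholds (percent RSD <= 2, recovery 98-102%).
#'
#' @param deltaLambda synchronous offset, nm.
#' @param derivativeInterval derivative window, points (odd, >= 3).
#' @param derivativeMode \code{"savgol"} or \code{"lagged"}.
#' @param measurementWavelengths named list of nm values or \code{"auto"}.
#' @param sensitivityFloor eligibility floor for measurement wavelengths,
#'   fraction of the analyte's maximum |1D|.
#' @param minFlank zero-crossing noise guard, AFU/nm.
#' @param calibrationLevels named list of ug/mL level vectors.
#' @param replicates calibration replicates per level.
#' @param noise a \linkS4class{NoiseModel}.
#' @param background flat background, AFU.
#' @param exGrid,emGrid scan axes, nm.
#' @param seed master seed.
#' @param rsdLimit,recoveryLow,recoveryHigh acceptance thresholds.
#' @return a \linkS4class{RunConfig}.
#' @examples
#' cfg <- runConfig()
#' deltaLambda(cfg)          # 80
#' cfg@derivativeInterval    # 15
#' @export
runConfig <- function(deltaLambda = 80,
                      derivativeInterval = 15,
                      derivativeMode = "savgol",
                      measurementWavelengths = list(ASP = "auto", ATO = "auto"),
                      sensitivityFloor = 0.2,
                      minFlank = 0,
                      calibrationLevels = list(
                        ATO = c(0.4, 1.5, 2.6, 3.7, 4.9, 6),
                        ASP = c(1, 2.8, 4.6, 6.4, 8.2, 10)),
                      replicates = 3,
                      noise = defaultNoise(),
                      background = 2,
                      exGrid = wavelengthGrid(220, 500, 1),
                      emGrid = wavelengthGrid(250, 600, 1),
                      seed = 42,
                      rsdLimit = 2,
                      recoveryLow = 98,
                      recoveryHigh = 102) {
  new("RunConfig",
      deltaLambda = as.numeric(deltaLambda),
      derivativeInterval = as.integer(derivativeInterval),
      derivativeMode = derivativeMode,
      measurementWavelengths = measurementWavelengths,
      sensitivityFloor = as.numeric(sensitivityFloor),
      minFlank = as.numeric(minFlank),
      calibrationLevels = calibrationLevels,
      replicates = as.integer(replicates),
      noise = noise,
      background = as.numeric(background),
      exGrid = exGrid, emGrid = emGrid,
      seed = as.integer(seed),
      rsdLimit = as.numeric(rsdLimit),
      recoveryLow = as.numeric(recoveryLow),
      recoveryHigh = as.numeric(recoveryHigh))
}

#' Load a run configuration from YAML
#'
#' Unspecified keys take the defaults of [runConfig()] (delta-lambda 80 nm,
#' 15-point window, automatic measurement wavelengths). Recognised keys:
#' \code{delta_lambda, derivative_interval, derivative_mode,
#' measurement_wavelengths (map analyte -> nm or "auto"), sensitivity_floor,
#' min_flank, calibration_levels (map analyte -> list), replicates,
#' noise: \{additive_sd, proportional_cv\}, background,
#' ex_grid / em_grid: \{start, stop, step\}, seed, rsd_limit, recovery_low,
#' recovery_high}.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return a \linkS4class{RunConfig}.
#' @export
loadConfig <- function(path = NULL) {
  y <- if (is.null(path)) list() else {
    if (!file.exists(path)) dataError("config file not found: %s", path)
    yaml::read_yaml(path)
  }
  if (is.null(y)) y <- list()
  args <- list()
  pick <- function(key, fn = identity) if (!is.null(y[[key]])) fn(y[[key]]) else NULL
  put <- function(name, val) if (!is.null(val)) args[[name]] <<- val
  put("deltaLambda", pick("delta_lambda", as.numeric))
  di <- pick("derivative_interval", as.integer)
  if (!is.null(di) && di %% 2L == 0L)
    dataError(paste0("derivative_interval must be odd (got %d): the window ",
                     "needs a centre point to assign the derivative to"), di)
  put("derivativeInterval", di)
  put("derivativeMode", pick("derivative_mode", as.character))
  put("measurementWavelengths", pick("measurement_wavelengths", as.list))
  put("sensitivityFloor", pick("sensitivity_floor", as.numeric))
  put("minFlank", pick("min_flank", as.numeric))
  put("calibrationLevels", pick("calibration_levels",
                                function(x) lapply(x, as.numeric)))
  put("replicates", pick("replicates", as.integer))
  if (!is.null(y$noise))
    args$noise <- noiseModel(
      additiveSd = if (is.null(y$noise$additive_sd)) 0 else y$noise$additive_sd,
      proportionalCv = if (is.null(y$noise$proportional_cv)) 0 else y$noise$proportional_cv)
  put("background", pick("background", as.numeric))
  gridFrom <- function(g) wavelengthGrid(g$start, g$stop,
                                         if (is.null(g$step)) 1 else g$step)
  if (!is.null(y$ex_grid)) args$exGrid <- gridFrom(y$ex_grid)
  if (!is.null(y$em_grid)) args$emGrid <- gridFrom(y$em_grid)
  put("seed", pick("seed", as.integer))
  put("rsdLimit", pick("rsd_limit", as.numeric))
  put("recoveryLow", pick("recovery_low", as.numeric))
  put("recoveryHigh", pick("recovery_high", as.numeric))
  do.call(runConfig, args)
}

#' @rdname deltaLambda
#' @export
setMethod("deltaLambda", "RunConfig", function(object) object@deltaLambda)

setMethod("show", "RunConfig", function(object) {
  mw <- vapply(object@measurementWavelengths, function(x) format(x), character(1))
  cat(sprintf(
    "RunConfig: delta-lambda %g nm, %d-point %s derivative, seed %d\n",
    object@deltaLambda, object@derivativeInterval, object@derivativeMode,
    object@seed))
  cat("  measurement wavelengths:",
      paste(sprintf("%s=%s", names(mw), mw), collapse = ", "), "\n")
  cat(sprintf("  noise: additive %g AFU, CV %g; background %g AFU\n",
              object@noise@additiveSd, object@noise@proportionalCv,
              object@background))
})
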