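#' @include workflows.R
NULL

#' ICH detection and quantification limits
#'
#' \code{LOD = 3.3 sigma / |S|}, \code{LOQ = 10 sigma / |S|}, where sigma
#' is the standard deviation of the calibration y-intercepts and S the
#' calibration slope. The two limits therefore always satisfy
#' \code{LOQ / LOD = 10 / 3.3}.
#'
#' @param sigmaIntercept sigma, AFU/nm; >= 0. A
#'   \linkS4class{CalibrationCurve} may be given instead, in which case
#'   its \code{sigmaIntercept} and \code{slope} are used.
#' @param slope calibration slope; non-zero.
#' @return named numeric: \code{lod}, \code{loq} (ug/mL).
#' @examples
#' lodLoq(0.0214, 0.4806)  # lod 0.1469, loq 0.4452
#' @export
lodLoq <- function(sigmaIntercept, slope) {
  if (is(sigmaIntercept, "CalibrationCurve")) {
    slope <- sigmaIntercept@slope
    sigmaIntercept <- sigmaIntercept@sigmaIntercept
  }
  if (is.na(sigmaIntercept) || sigmaIntercept < 0)
    dataError("'sigmaIntercept' must be available and >= 0")
  if (slope == 0) numericError("calibration slope is zero; LOD/LOQ undefined")
  c(lod = 3.3 * sigmaIntercept / abs(slope),
    loq = 10 * sigmaIntercept / abs(slope))
}

#' Precision summary of percent values
#'
#' Mean, sample (n-1) standard deviation and percent RSD
#' (\code{100 * sd / mean}) with a pass flag against the percent-RSD
#' acceptance limit (default 2.0%).
#'
#' @param values numeric, n >= 2; mean must be non-zero.
#' @param rsdLimit acceptance limit, percent.
#' @return list with \code{values, mean, sd, percentRsd, pass}.
#' @examples
#' precisionSummary(c(99.18, 98.57, 100.94, 98.72))  # mean 99.35, RSD 1.097
#' @export
precisionSummary <- function(values, rsdLimit = 2) {
  if (length(values) < 2L) dataError("precision needs >= 2 values")
  m <- mean(values)
  if (m == 0) numericError("mean of values is zero; percent RSD undefined")
  s <- stats::sd(values)
  rsd <- 100 * s / m
  list(values = values, mean = m, sd = s, percentRsd = rsd,
       pass = rsd <= rsdLimit)
}

#' Recovery (accuracy) study at 80/100/120% of the assay concentration
#'
#' Simulates mixtures of both analytes at the given fractions of their
#' assay concentrations (defaults 1 ug/mL ATO with 2 ug/mL ASP, i.e.
#' 0.8/1/1.2 and 1.6/2/2.4 ug/mL), in triplicate, quantifies them through
#' the calibrated pipeline and reports the mean percent recovery per
#' analyte with a pass flag against the recovery acceptance band
#' (default 98-102%).
#'
#' @param curves named list of \linkS4class{CalibrationCurve}.
#' @param config a \linkS4class{RunConfig}.
#' @param assayConc named ug/mL vector of the 100% level per analyte; all
#'   > 0 and inside each curve's validated range at every fraction.
#' @param fractions study levels as fractions of \code{assayConc}.
#' @param replicates determinations per level.
#' @param models,seed simulator settings (noise/background from config).
#' @return list with \code{determinations} (data.frame) and
#'   \code{summary} (per-analyte mean recovery, n, pass).
#' @export
accuracyStudy <- function(curves, config = runConfig(),
                          assayConc = c(ATO = 1, ASP = 2),
                          fractions = c(0.8, 1, 1.2), replicates = 3,
                          models = defaultModels(), seed = config@seed) {
  if (any(assayConc <= 0))
    dataError("assay concentrations must be > 0 (a fraction of zero is meaningless)")
  for (a in names(assayConc)) {
    cu <- curves[[a]]
    if (is.null(cu)) dataError("no calibration curve for analyte '%s'", a)
    lv <- assayConc[[a]] * fractions
    if (any(lv < cu@rangeLow | lv > cu@rangeHigh))
      dataError("accuracy level for '%s' falls outside the validated range %g-%g ug/mL",
                a, cu@rangeLow, cu@rangeHigh)
  }
  rows <- list()
  k <- 0L
  for (f in fractions) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      conc <- assayConc * f
      eem <- simulateEEM(models, conc[names(models)],
                         config@exGrid, config@emGrid,
                         noise = config@noise, background = config@background,
                         seed = childSeed(seed, 7000L + k))
      res <- analyzeMixture(eem, curves, config, analytes = names(assayConc))
      res$fraction <- f
      res$replicate <- r
      rows[[k]] <- res
    }
  }
  determinations <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(names(assayConc), function(a) {
    rec <- determinations$percent_recovery[determinations$analyte == a]
    data.frame(analyte = a, mean_recovery = mean(rec), n = length(rec),
               pass = mean(rec) >= config@recoveryLow &
                 mean(rec) <= config@recoveryHigh)
  }))
  list(determinations = determinations, summary = summary)
}

#' Repeatability / intermediate precision study
#'
#' Quantifies three concentration levels per analyte (defaults: ATO 1, 2,
#' 3 and ASP 2, 4, 6 ug/mL) in triplicate through the calibrated pipeline.
#' With \code{days = 1} this is repeatability (nine same-day
#' determinations); with \code{days > 1} each day re-runs the levels under
#' a day-offset seed, emulating intermediate precision.
#'
#' @param curves named list of \linkS4class{CalibrationCurve}.
#' @param config a \linkS4class{RunConfig}.
#' @param levels named list of the three study levels per analyte (ug/mL).
#' @param replicates determinations per level per day.
#' @param days number of days.
#' @param models,seed simulator settings.
#' @return list with \code{determinations} and \code{summary}
#'   (per-analyte percent RSD of all recoveries, with pass flag).
#' @export
precisionStudy <- function(curves, config = runConfig(),
                           levels = list(ATO = c(1, 2, 3), ASP = c(2, 4, 6)),
                           replicates = 3, days = 1,
                           models = defaultModels(), seed = config@seed) {
  rows <- list()
  k <- 0L
  for (day in seq_len(days)) {
    for (a in names(levels)) {
      for (lv in levels[[a]]) {
        for (r in seq_len(replicates)) {
          k <- k + 1L
          conc <- stats::setNames(numeric(length(models)), names(models))
          conc[a] <- lv
          eem <- simulateEEM(models, conc, config@exGrid, config@emGrid,
                             noise = config@noise, background = config@background,
                             seed = childSeed(seed, 11000L + 997L * day + k))
          res <- analyzeMixture(eem, curves, config, analytes = a)
          res$day <- day
          res$replicate <- r
          rows[[k]] <- res
        }
      }
    }
  }
  determinations <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(names(levels), function(a) {
    rec <- determinations$percent_recovery[determinations$analyte == a]
    ps <- precisionSummary(rec, rsdLimit = config@rsdLimit)
    data.frame(analyte = a, percent_rsd = ps$percentRsd, n = length(rec),
               pass = ps$pass)
  }))
  list(determinations = determinations, summary = summary)
}

#' Two-method t/F comparison
#'
#' Pooled-variance two-sample t test on the absolute difference of mean
#' recoveries (reported unsigned) and the variance-ratio F in the
#' larger/smaller convention, with two-tailed 95% critical t and upper-5%
#' critical F for the corresponding degrees of freedom.
#'
#' @param n1,mean1,var1 size, mean percent recovery and variance of the
#'   first method. Alternatively \code{n1} may be a numeric vector of raw
#'   recoveries (then \code{mean1}/\code{var1} are computed from it), and
#'   likewise \code{n2}.
#' @param n2,mean2,var2 the second method.
#' @return a \linkS4class{MethodComparison}.
#' @examples
#' compareMethods(5, 99.83, 1.269, 5, 100.48, 1.743)
#' @export
compareMethods <- function(n1, mean1 = NULL, var1 = NULL,
                           n2, mean2 = NULL, var2 = NULL) {
  if (length(n1) > 1L) { mean1 <- mean(n1); var1 <- stats::var(n1); n1 <- length(n1) }
  if (length(n2) > 1L) { mean2 <- mean(n2); var2 <- stats::var(n2); n2 <- length(n2) }
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 2L || n2 < 2L) dataError("both methods need n >= 2")
  if (var1 == 0 && var2 == 0)
    numericError("both variances are zero; t and F are undefined")
  dfT <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * var1 + (n2 - 1) * var2) / dfT
  tStat <- abs(mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  if (var1 >= var2) {
    fStat <- if (var2 > 0) var1 / var2 else Inf
    dfF <- c(n1 - 1L, n2 - 1L)
  } else {
    fStat <- var2 / var1
    dfF <- c(n2 - 1L, n1 - 1L)
  }
  new("MethodComparison",
      n1 = n1, n2 = n2, mean1 = mean1, mean2 = mean2,
      var1 = var1, var2 = var2,
      tStatistic = tStat, fStatistic = fStat,
      dfT = dfT, dfF = dfF,
      criticalT = stats::qt(0.975, dfT),
      criticalF = stats::qf(0.95, dfF[1], dfF[2]))
}

setMethod("show", "MethodComparison", function(object) {
  cat(sprintf("MethodComparison (n = %d vs %d)\n", object@n1, object@n2))
  cat(sprintf("  means %.3f vs %.3f, variances %.4g vs %.4g\n",
              object@mean1, object@mean2, object@var1, object@var2))
  cat(sprintf("  t = %.3f (critical %.3f at df %d), F = %.3f (critical %.3f at df %d,%d)\n",
              object@tStatistic, object@criticalT, object@dfT,
              object@fStatistic, object@criticalF, object@dfF[1], object@dfF[2]))
})

#' Robustness sweep over pipeline perturbations
#'
#' Determines three concentrations of each drug (pure samples at the
#' precision study levels) with one operating parameter deliberately
#' perturbed, one axis at a time, and reports per analyte the percent RSD
#' of those determinations' recoveries under the perturbed condition (the
#' worst of the -delta and +delta runs). This is the compendial robustness
#' statistic: a condition change that rescales all determinations equally
#' leaves it small, exactly as a rugged method should. The systematic
#' spread is reported separately as \code{sensitivity_rsd}: the percent
#' RSD of the per-condition mean recoveries across \code{-delta, 0,
#' +delta}, which isolates how strongly the result responds to the knob
#' itself (for a pure proportional perturbation of size d it approaches
#' 100 d).
#'
#' Supported axes: \describe{
#'   \item{deltaLambda}{the synchronous offset, perturbed by +/- delta nm
#'     (|delta| <= 5) while measurement wavelengths and curves stay at the
#'     base setting.}
#'   \item{brightness}{a fractional jitter of every fluorophore's
#'     brightness (|delta| <= 0.1), the simulator's stand-in for the
#'     wet-chemistry factors (pH, buffer volume) that scale fluorescence
#'     yield.}
#' }
#'
#' @param config a \linkS4class{RunConfig}; its noise model and seed drive
#'   the simulated determinations.
#' @param curves named list of \linkS4class{CalibrationCurve}.
#' @param levels named list of the three study levels per analyte, ug/mL.
#' @param axes named list of perturbation magnitudes, e.g.
#'   \code{list(deltaLambda = 1, brightness = 0.01)}.
#' @param models simulator band models.
#' @return data.frame with columns \code{axis, delta, analyte,
#'   percent_rsd, sensitivity_rsd, pass}.
#' @export
robustnessSweep <- function(config, curves,
                            levels = list(ATO = c(1, 2, 3), ASP = c(2, 4, 6)),
                            axes = list(deltaLambda = 1, brightness = 0.01),
                            models = defaultModels()) {
  levels <- levels[names(levels) %in% names(curves)]
  rows <- list()
  k <- 0L
  for (axis in names(axes)) {
    delta <- axes[[axis]]
    if (axis == "deltaLambda" && abs(delta) > 5)
      dataError("deltaLambda perturbation must be within +/- 5 nm")
    if (axis == "brightness" && abs(delta) > 0.1)
      dataError("brightness jitter must be within +/- 10%%")
    if (!axis %in% c("deltaLambda", "brightness"))
      dataError("unknown robustness axis '%s'", axis)
    conds <- c(-delta, 0, delta)
    # recoveries[[analyte]][level, condition]
    recov <- lapply(levels, function(lv)
      matrix(NA_real_, length(lv), length(conds)))
    for (ci in seq_along(conds)) {
      d <- conds[ci]
      cfg <- config
      mods <- models
      if (axis == "deltaLambda") cfg@deltaLambda <- config@deltaLambda + d
      if (axis == "brightness")
        mods <- lapply(models, function(m) {
          m@brightness <- m@brightness * (1 + d); m })
      for (a in names(levels)) {
        for (li in seq_along(levels[[a]])) {
          k <- k + 1L
          conc <- stats::setNames(numeric(length(mods)), names(mods))
          conc[a] <- levels[[a]][li]
          eem <- simulateEEM(mods, conc, config@exGrid, config@emGrid,
                             noise = config@noise,
                             background = config@background,
                             seed = childSeed(config@seed, 21000L + k))
          found <- quantifyEEM(eem, curves[a], cfg)$found
          recov[[a]][li, ci] <- 100 * found / levels[[a]][li]
        }
      }
    }
    for (a in names(levels)) {
      m <- recov[[a]]
      perCond <- apply(m, 2, function(r) 100 * stats::sd(r) / mean(r))
      worst <- if (any(conds != 0)) max(perCond[conds != 0]) else perCond[1]
      condMeans <- colMeans(m)
      sens <- 100 * stats::sd(condMeans) / mean(condMeans)
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, delta = delta, analyte = a, percent_rsd = worst,
        sensitivity_rsd = sens, pass = worst <= config@rsdLimit)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
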