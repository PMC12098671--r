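test_that("detection limits follow the 3.3/10 sigma-over-slope formulas", {
  expect_equal(lodLoq(0, 0.5), c(lod = 0, loq = 0))
  lim <- lodLoq(0.0214, 0.4806)
  expect_equal(lim[["lod"]], 3.3 * 0.0214 / 0.4806, tolerance = 1e-12)
  expect_equal(lim[["loq"]], 10 * 0.0214 / 0.4806, tolerance = 1e-12)
  expect_equal(lim[["lod"]], 0.14694, tolerance = 1e-4)
  expect_equal(lim[["loq"]], 0.44528, tolerance = 1e-4)
  # the ratio is forced by the formulas, whatever sigma and slope
  set.seed(3)
  for (k in 1:10) {
    lim <- lodLoq(runif(1, 0.001, 1), runif(1, -2, 2))
    expect_equal(lim[["loq"]] / lim[["lod"]], 10 / 3.3, tolerance = 1e-12)
  }
  expect_error(lodLoq(0.1, 0), "slope")
})

test_that("precision summaries reproduce the reported study statistics", {
  # standard-addition pure recoveries, per analyte
  ato <- precisionSummary(c(99.18, 98.57, 100.94, 98.72))
  expect_equal(ato$mean, 99.35, tolerance = 1e-3)
  expect_equal(ato$percentRsd, 1.097, tolerance = 5e-4)
  expect_true(ato$pass)
  asp <- precisionSummary(c(101.28, 99.40, 100.65, 101.83))
  expect_equal(asp$mean, 100.79, tolerance = 1e-3)
  expect_equal(asp$percentRsd, 1.036, tolerance = 5e-4)
  expect_equal(precisionSummary(rep(50, 4))$percentRsd, 0)
  expect_error(precisionSummary(c(-1, 1)), "mean")
  expect_error(precisionSummary(99), ">= 2")
  # one-pass and two-pass SD agree
  set.seed(11)
  x <- rnorm(20, 100, 2)
  onePass <- sqrt((sum(x^2) - length(x) * mean(x)^2) / (length(x) - 1))
  twoPass <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  ps <- precisionSummary(x)
  expect_equal(ps$sd, twoPass, tolerance = 1e-12)
  expect_equal(onePass, twoPass, tolerance = 1e-12)
})

test_that("method comparison reproduces the reported F and critical values", {
  cmp <- compareMethods(5, 99.83, 1.269, 5, 100.48, 1.743)
  expect_equal(cmp@fStatistic, 1.373, tolerance = 1e-3)
  expect_equal(cmp@criticalF, 6.388, tolerance = 1e-3)
  expect_equal(cmp@criticalT, 2.306, tolerance = 1e-3)
  expect_equal(cmp@dfT, 8L)
  cmp2 <- compareMethods(5, 99.8, 0.09, 5, 99.85, 0.23)
  expect_equal(cmp2@fStatistic, 2.556, tolerance = 1e-3)
  # identical summaries -> t = 0, F = 1
  same <- compareMethods(5, 100, 1, 5, 100, 1)
  expect_equal(same@tStatistic, 0)
  expect_equal(same@fStatistic, 1)
  expect_error(compareMethods(5, 100, 0, 5, 100, 0), "variance")
})

test_that("summary-based t equals the brute-force pooled t on raw vectors", {
  set.seed(21)
  for (k in 1:8) {
    x <- rnorm(sample(4:8, 1), 100, 1.5)
    y <- rnorm(sample(4:8, 1), 100.5, 1)
    cmp <- compareMethods(x, n2 = y)
    oracle <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(cmp@tStatistic, abs(unname(oracle$statistic)),
                 tolerance = 1e-10)
    # F is invariant to argument order
    rev <- compareMethods(y, n2 = x)
    expect_equal(cmp@fStatistic, rev@fStatistic, tolerance = 1e-12)
    expect_gte(cmp@fStatistic, 1)
  }
})

test_that("accuracy study passes the recovery band and guards its inputs", {
  cfg <- quietConfig()
  curves <- noiselessCurves()
  res <- accuracyStudy(curves, cfg, replicates = 1, seed = 30)
  expect_equal(nrow(res$determinations), 6)
  expect_true(all(res$summary$mean_recovery >= 99.5 &
                    res$summary$mean_recovery <= 100.5))
  expect_true(all(res$summary$pass))
  noisyCfg <- runConfig()
  resN <- accuracyStudy(noisyCurves(), noisyCfg, seed = 31)
  expect_true(all(resN$summary$mean_recovery >= 98 &
                    resN$summary$mean_recovery <= 102))
  expect_error(accuracyStudy(curves, cfg, assayConc = c(ATO = 0, ASP = 2)),
               "> 0")
  expect_error(accuracyStudy(curves, cfg, assayConc = c(ATO = 40, ASP = 2)),
               "range")
})

test_that("robustness is insensitive to the documented perturbations", {
  cfg <- quietConfig()
  curves <- noiselessCurves()
  rob <- robustnessSweep(cfg, curves,
                         axes = list(deltaLambda = 1, brightness = 0.01))
  expect_true(all(rob$percent_rsd <= 2))
  # brightness jitter propagates linearly into the sensitivity measure:
  # a pure proportional perturbation of 1% shows up as ~1% spread
  bright <- rob$sensitivity_rsd[rob$axis == "brightness"]
  expect_equal(bright, rep(1, 2), tolerance = 0.05)
  zero <- robustnessSweep(cfg, curves, axes = list(brightness = 0))
  expect_equal(zero$percent_rsd, rep(0, 2), tolerance = 1e-9)
  expect_equal(zero$sensitivity_rsd, rep(0, 2), tolerance = 1e-9)
  expect_error(robustnessSweep(cfg, curves, axes = list(deltaLambda = 20)),
               "5 nm")
})

test_that("validation reports render completely and round-trip", {
  block <- function(lod) list(
    wavelength = 384, rangeLow = 0.4, rangeHigh = 6, rSquared = 0.9998,
    intercept = 0.02, slope = 1.19, lod = lod, loq = 10 / 3.3 * lod,
    accuracy = 99.9, repeatability = 0.6, intermediatePrecision = 0.8,
    robustness = c(deltaLambda = 0.4, brightness = 1.0))
  rep1 <- buildValidationReport(list(ATO = block(0.05), ASP = block(0.11)))
  path <- withr::local_tempfile(fileext = ".csv")
  renderReport(rep1, path)
  tab <- read.csv(path, comment.char = "#")
  labels <- c("wavelength", "linearity_range_low", "linearity_range_high",
              "r_squared", "intercept", "slope", "lod", "loq", "accuracy",
              "repeatability", "intermediate_precision",
              "robustness_deltaLambda", "robustness_brightness")
  expect_setequal(unique(tab$parameter), labels)
  expect_false(any(grepl("WARNING", readLines(paste0(path, ".txt")))))
  expect_equal(tab$value[tab$analyte == "ATO" & tab$parameter == "slope"], 1.19)
  # an inconsistent LOQ/LOD pair triggers the embedded warning
  badBlock <- block(0.05); badBlock$loq <- 0.4
  rep2 <- buildValidationReport(list(ATO = badBlock))
  renderReport(rep2, path)
  expect_true(any(grepl("WARNING.*LOQ/LOD", readLines(paste0(path, ".txt")))))
  # missing entries are named
  expect_error(buildValidationReport(list(ATO = block(0.05)[-3])),
               "rangeHigh")
})
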