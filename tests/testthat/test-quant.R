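# brute-force re-implementation of the documented wavelength objective:
# candidates = non-edge grid points + interpolated interferent crossings;
# minimise worst-case relative interference (interferent |1D| / analyte
# |1D|) subject to the sensitivity floor, ties towards the strongest
# analyte |1D|
bruteForceSelect <- function(interfDerivs, analyteDeriv, floor = 0.2) {
  w <- wavelengths(analyteDeriv)
  e <- 7L
  cand <- sort(c(w[(e + 1):(length(w) - e)],
                 unlist(lapply(interfDerivs, findZeroCrossings))))
  ref <- abs(vapply(cand, function(x) amplitudeAt(analyteDeriv, x), numeric(1)))
  keep <- ref >= floor * max(ref)
  cand <- cand[keep]; ref <- ref[keep]
  worst <- vapply(cand, function(x)
    max(vapply(interfDerivs, function(d) abs(amplitudeAt(d, x)), numeric(1))),
    numeric(1)) / ref
  tied <- which(worst <= min(worst) + 1e-12 * (min(worst) + 1))
  cand[tied[which.max(ref[tied])]]
}

test_that("measurement wavelengths sit at the interferent zero crossings", {
  curves <- noiselessCurves()
  expect_lt(abs(curves$ATO@wavelength - 384), 10)
  expect_lt(abs(curves$ASP@wavelength - 365), 10)
})

test_that("wavelength selection equals the brute-force scan of its objective", {
  m <- defaultModels()
  interf <- lapply(c(2, 5, 8), function(cc) pureDeriv(m$ASP, cc))
  ref <- pureDeriv(m$ATO, 4)
  expect_equal(selectMeasurementWavelength(interf, ref),
               bruteForceSelect(interf, ref))
  # degenerate rule: no interferent signal -> strongest analyte wavelength
  zero <- interf[[1]]
  zero@amplitudes <- rep(0, length(zero@amplitudes))
  lam <- selectMeasurementWavelength(list(zero), ref)
  a <- abs(amplitudes(ref)); core <- 8:(length(a) - 7)
  expect_equal(lam, wavelengths(ref)[core][which.max(a[core])])
})

test_that("calibration fitting reproduces exact lines and replicate sigma", {
  cu <- fitCalibration(c(0, 1, 2), c(1, 3, 5))
  expect_equal(cu@slope, 2)
  expect_equal(cu@intercept, 1)
  expect_equal(cu@r, 1)
  expect_true(is.na(cu@sigmaIntercept))
  expect_error(fitCalibration(c(1, 1, 1), c(1, 2, 3)), "distinct")
  # replicate refits expose intercept scatter
  set.seed(5)
  conc <- rep(c(1, 2, 4, 8), 3)
  reps <- rep(1:3, each = 4)
  amps <- 0.5 * conc + rep(rnorm(3, 0, 0.1), each = 4)
  cu <- fitCalibration(conc, amps, replicates = reps)
  perRep <- vapply(1:3, function(r)
    coef(lm(amps[reps == r] ~ conc[reps == r]))[[1]], numeric(1))
  expect_equal(cu@sigmaIntercept, sd(perRep))
})

test_that("noiseless default calibrations are linear to the reported floor", {
  curves <- noiselessCurves()
  expect_gte(curves$ATO@rSquared, 0.9998)
  expect_gte(curves$ASP@rSquared, 0.9998)
})

test_that("inverse prediction inverts the line and flags extrapolation", {
  curve <- new("CalibrationCurve", analyte = "ATO", wavelength = 384,
               slope = 0.2138, intercept = 3.9893, r = 0.9999,
               rSquared = 0.9998, sigmaIntercept = NA_real_,
               rangeLow = 0.4, rangeHigh = 6, n = 6L)
  expect_equal(as.numeric(predictConcentration(curve, 4.4169)), 2.0,
               tolerance = 1e-9)
  atIntercept <- predictConcentration(curve, 3.9893)
  expect_equal(as.numeric(atIntercept), 0)
  expect_true(attr(atIntercept, "outOfRange"))
  bad <- curve; bad@slope <- 0
  expect_error(predictConcentration(bad, 1), "slope")
  # predict o fit is the identity on a perfect line
  cu <- fitCalibration(c(1, 2, 3, 4), c(2.2, 4.4, 6.6, 8.8))
  expect_equal(as.numeric(predictConcentration(cu, c(2.2, 6.6))), c(1, 3),
               tolerance = 1e-12)
})

test_that("mixture analysis recovers noiseless compositions end to end", {
  cfg <- quietConfig()
  curves <- noiselessCurves()
  mix <- mixturePanel(noise = noiseless(), seed = 2)
  res <- do.call(rbind, lapply(mix, analyzeMixture, curves = curves, config = cfg))
  expect_true(all(res$percent_recovery >= 98 & res$percent_recovery <= 102))
  # recovery arithmetic matches the reported convention
  expect_equal(100 * 1.899 / 1.875, 101.28)
  # blank sample flags both analytes below range
  blank <- mixturePanel(data.frame(ASP = 0, ATO = 0), noise = noiseless(),
                        seed = 1)[[1]]
  resB <- analyzeMixture(blank, curves, cfg)
  expect_true(all(resB$out_of_range))
  expect_error(analyzeMixture(blank, curves, cfg, analytes = "XYZ"), "XYZ")
})

test_that("recovery is invariant to a 3-fold co-analyte change", {
  cfg <- quietConfig()
  curves <- noiselessCurves()
  m <- defaultModels()
  for (a in c("ATO", "ASP")) {
    other <- setdiff(names(m), a)
    mid <- c(ATO = 2, ASP = 4)[[a]]
    recs <- vapply(c(1, 2, 3), function(f) {
      conc <- setNames(c(mid, f * c(ATO = 1, ASP = 2)[[other]]), c(a, other))
      eem <- simulateEEM(m[c(a, other)], conc)
      analyzeMixture(eem, curves, cfg, analytes = a)$percent_recovery
    }, numeric(1))
    expect_lt(max(abs(recs - recs[1])) / recs[1], 0.01)
  }
})

test_that("standard addition follows the subtraction accounting", {
  rec <- standardAddition(75.21, 7.5, 82.847)
  expect_equal(rec$pure_found, 7.637)
  expect_equal(round(rec$percent_recovery, 2), 101.83)
  expect_false(rec$flagged)
  expect_equal(standardAddition(10, 2.5, 12.5)$percent_recovery, 100)
  flagged <- standardAddition(10, 1, 9.5)
  expect_true(flagged$flagged)
  expect_error(standardAddition(10, 0, 12), "added")
})

test_that("tablet assays report recovery against label claim", {
  cfg <- quietConfig()
  curves <- noiselessCurves()
  m <- defaultModels()
  atoLevels <- c(0.8, 1.2, 1.6, 2, 2.4)
  nominal <- data.frame(ATO = atoLevels, ASP = 3.75 * atoLevels)
  makeEEMs <- function(scale) lapply(seq_len(nrow(nominal)), function(i)
    simulateEEM(m, c(ASP = scale * nominal$ASP[i], ATO = scale * nominal$ATO[i]),
                background = 2))
  res <- tabletAssay(makeEEMs(1), nominal, curves, cfg)
  expect_equal(res$summary$mean_recovery, c(100, 100), tolerance = 0.005)
  expect_true(all(res$summary$rsd <= 2))
  # 99% content shows up as ~99% recovery
  res99 <- tabletAssay(makeEEMs(0.99), nominal, curves, cfg)
  expect_equal(res99$summary$mean_recovery, c(99, 99), tolerance = 0.01)
  expect_warning(
    tabletAssay(makeEEMs(1)[1:4], nominal[1:4, ], curves, cfg), "5 dilution")
})
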