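refinePeak <- function(w, y) {
  # parabolic refinement of a gridded maximum (independent of the package)
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(w[i])
  num <- y[i - 1] - y[i + 1]
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  w[i] + 0.5 * num / den * (w[2] - w[1])
}

test_that("synchronous peak matches the product-of-Gaussians closed form", {
  set.seed(101)
  for (k in 1:25) {
    exMax <- runif(1, 250, 320)
    emMax <- exMax + runif(1, 50, 120)
    sx <- runif(1, 15, 40); sm <- runif(1, 15, 40)
    dl <- runif(1, 40, 100)
    m <- fluorophore("rand", exMax, emMax, sx, sm, brightness = 50)
    theory <- syncPeakTheory(m, dl)
    eem <- simulateEEM(list(m), 2, wavelengthGrid(200, 420, 1),
                       wavelengthGrid(240, 560, 1))
    s <- synchronousSpectrum(eem, dl)
    skip_if(theory < min(wavelengths(s)) + 5 || theory > max(wavelengths(s)) - 5)
    expect_lt(abs(refinePeak(wavelengths(s), intensities(s)) - theory), 0.5)
  }
})

test_that("synchronous slicing is linear and handles degenerate inputs", {
  ex <- wavelengthGrid(250, 350, 1); em <- wavelengthGrid(300, 460, 1)
  z <- simulateEEM(list(), numeric(0), ex, em)
  expect_true(all(intensities(synchronousSpectrum(z, 60)) == 0))
  m <- defaultModels()
  mix <- simulateEEM(m, c(ASP = 6, ATO = 2), ex, em)
  pureA <- simulateEEM(m["ASP"], 6, ex, em)
  pureT <- simulateEEM(m["ATO"], 2, ex, em)
  expect_equal(intensities(synchronousSpectrum(mix, 60)),
               intensities(synchronousSpectrum(pureA, 60)) +
                 intensities(synchronousSpectrum(pureT, 60)))
  # insufficient overlap reports the usable range
  expect_error(synchronousSpectrum(z, 300), "overlap")
})

test_that("first derivative is exact on polynomials and locates Gaussian peaks", {
  w <- wavelengthGrid(300, 400, 1)
  flat <- new("FluorSpectrum", axisKind = "emission", wavelengths = w,
              intensities = rep(5, length(w)), meta = list())
  expect_true(all(abs(amplitudes(firstDerivative(flat, 15))) < 1e-12))
  ramp <- new("FluorSpectrum", axisKind = "emission", wavelengths = w,
              intensities = 2 + 0.31 * w, meta = list())
  for (mode in c("savgol", "lagged")) {
    d <- firstDerivative(ramp, 15, mode)
    expect_equal(amplitudes(d)[8:94], rep(0.31, 87), tolerance = 1e-9)
  }
  gauss <- new("FluorSpectrum", axisKind = "emission", wavelengths = w,
               intensities = exp(-(w - 352.3)^2 / (2 * 15^2)), meta = list())
  cross <- findZeroCrossings(firstDerivative(gauss, 15))
  expect_length(cross, 1)
  expect_lt(abs(cross - 352.3), 1)
  expect_error(firstDerivative(gauss, 14), "odd")
  expect_error(firstDerivative(gauss, 61), "short")
})

test_that("the derivative operator is linear", {
  m <- defaultModels()
  sA <- synchronousSpectrum(simulateEEM(m["ASP"], 4), 80)
  sT <- synchronousSpectrum(simulateEEM(m["ATO"], 2), 80)
  combo <- new("SyncSpectrum", axisKind = "synchronous-emission",
               wavelengths = wavelengths(sA),
               intensities = 2.5 * intensities(sA) - 1.25 * intensities(sT),
               deltaLambda = 80, meta = list())
  expect_equal(amplitudes(firstDerivative(combo, 15)),
               2.5 * amplitudes(firstDerivative(sA, 15)) -
                 1.25 * amplitudes(firstDerivative(sT, 15)),
               tolerance = 1e-9)
})

test_that("zero-crossing search matches a brute-force sign scan", {
  m <- defaultModels()
  mix <- simulateEEM(m, c(ASP = 5, ATO = 3))
  d <- firstDerivative(synchronousSpectrum(mix, 80), 15)
  found <- findZeroCrossings(d)
  # oracle: count strict sign changes over all adjacent non-edge pairs
  a <- amplitudes(d)
  e <- 7L
  core <- (e + 1L):(length(a) - e)
  oracle <- sum(a[core[-length(core)]] * a[core[-1]] < 0)
  expect_length(found, oracle)
  # strictly positive array -> no crossings
  pos <- new("DerivSpectrum", wavelengths = wavelengths(d),
             amplitudes = abs(a) + 1, interval = 15L, meta = list(edge = 7L))
  expect_length(findZeroCrossings(pos), 0)
  # the flank guard suppresses shallow crossings
  guarded <- findZeroCrossings(d, minFlank = max(abs(a)) * 2)
  expect_length(guarded, 0)
})

test_that("zero-crossing refinement lands within half a grid step of theory", {
  set.seed(202)
  for (k in 1:10) {
    m <- fluorophore("rand", runif(1, 260, 300), runif(1, 360, 420),
                     runif(1, 20, 35), runif(1, 20, 35), 80)
    d <- pureDeriv(m, 3, dl = 80)
    theory <- syncPeakTheory(m, 80)
    cross <- findZeroCrossings(d)
    expect_lt(min(abs(cross - theory)), 0.5)
  }
})

test_that("amplitude lookup interpolates linearly and guards its range", {
  d <- new("DerivSpectrum", wavelengths = seq(300, 310, 1),
           amplitudes = c(0, 1, 4, 9, 16, 25, 36, 49, 64, 81, 100),
           interval = 3L, meta = list(edge = 1L))
  expect_equal(amplitudeAt(d, 305), 25)
  expect_equal(amplitudeAt(d, 305.5), (25 + 36) / 2)
  expect_error(amplitudeAt(d, 299), "outside")
})

test_that("interferent-channel amplitude responds linearly to the analyte", {
  # 1D at the ASP zero crossing scales with ATO concentration
  curves <- noiselessCurves()
  lambdaATO <- curves$ATO@wavelength
  m <- defaultModels()
  concs <- c(0.5, 1.5, 3, 4.5, 6)
  amps <- vapply(concs, function(cc)
    amplitudeAt(pureDeriv(m$ATO, cc), lambdaATO), numeric(1))
  expect_gt(cor(amps, concs)^2, 0.9999)
})

test_that("delta-lambda scan scores candidates and degrades gracefully", {
  cfg <- quietConfig()
  panels <- purePanelsNoiseless()
  single <- scanDeltaLambda(panels, 80, cfg)
  expect_equal(single$best, 80)
  # identical analytes cannot be resolved
  m <- defaultModels()
  same <- list(
    A = calibrationPanel("A", c(1, 3), replicates = 1, noise = noiseless(),
                         seed = 1, models = list(A = m$ASP, B = m$ASP)),
    B = calibrationPanel("B", c(1, 3), replicates = 1, noise = noiseless(),
                         seed = 1, models = list(A = m$ASP, B = m$ASP)))
  res <- scanDeltaLambda(same, 80, cfg)
  expect_equal(res$table$score, 0)
  expect_equal(res$table$note, "unresolvable")
})
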