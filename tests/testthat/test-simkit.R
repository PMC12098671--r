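test_that("band intensity follows the separable Gaussian response", {
  m <- fluorophore("X", exMax = 285, emMax = 405, exWidth = 28,
                   emWidth = 30, brightness = 120)
  expect_equal(bandIntensity(m, 285, 405), 120)
  expect_equal(bandIntensity(m, 285, 435), 120 * exp(-0.5))
  expect_equal(bandIntensity(m, 285 + 28, 405), 120 * exp(-0.5))
  # emission maxima of the default pair sit at the native wavelengths
  em <- wavelengthGrid(200, 600, 1)
  d <- defaultModels()
  expect_equal(em[which.max(bandIntensity(d$ASP, 285, em))], 405)
  expect_equal(em[which.max(bandIntensity(d$ATO, 300, em))], 364)
})

test_that("fluorophore validity rejects unphysical band models", {
  expect_error(fluorophore("X", 300, 280, 20, 20, 1), "Stokes")
  expect_error(fluorophore("X", 280, 300, -5, 20, 1), "exWidth")
  expect_error(fluorophore("X", 280, 300, 20, 20, -1), "brightness")
})

test_that("simulated EEMs are linear, additive and reproducible", {
  m <- defaultModels()
  ex <- wavelengthGrid(250, 350, 5); em <- wavelengthGrid(300, 450, 5)
  # empty model list, no background -> all zero
  z <- simulateEEM(list(), numeric(0), ex, em)
  expect_true(all(intensities(z) == 0))
  # exact doubling
  e1 <- simulateEEM(m["ASP"], 2, ex, em)
  e2 <- simulateEEM(m["ASP"], 4, ex, em)
  expect_equal(intensities(e2), 2 * intensities(e1))
  # mixture equals the elementwise sum of pures plus background
  mix <- simulateEEM(m, c(ASP = 6, ATO = 2), ex, em, background = 3)
  pureA <- simulateEEM(m["ASP"], 6, ex, em)
  pureT <- simulateEEM(m["ATO"], 2, ex, em)
  expect_equal(intensities(mix),
               intensities(pureA) + intensities(pureT) + 3)
  # negative concentration names the offender
  expect_error(simulateEEM(m, c(ASP = -1, ATO = 2), ex, em), "ASP")
  # identical seed -> bit-identical; different seed -> different draw
  n <- defaultNoise()
  a <- simulateEEM(m, c(ASP = 2, ATO = 1), ex, em, noise = n, seed = 99)
  b <- simulateEEM(m, c(ASP = 2, ATO = 1), ex, em, noise = n, seed = 99)
  c <- simulateEEM(m, c(ASP = 2, ATO = 1), ex, em, noise = n, seed = 100)
  expect_identical(intensities(a), intensities(b))
  expect_false(identical(intensities(a), intensities(c)))
  expect_error(simulateEEM(m, c(ASP = 2, ATO = 1), ex, em, noise = n),
               "seed")
})

test_that("calibration panels have the declared layout and determinism", {
  ex <- wavelengthGrid(250, 350, 5); em <- wavelengthGrid(300, 450, 5)
  p <- calibrationPanel("ATO", levels = c(0.4, 2, 6), replicates = 2,
                        noise = noiseless(), seed = 5,
                        exWavelengths = ex, emWavelengths = em)
  expect_length(p, 6)
  sheet <- panelSheet(p)
  expect_setequal(unique(sheet$analyte), c("ASP", "ATO"))
  # zero noise -> replicate EEMs at one level are identical
  p1 <- calibrationPanel("ASP", levels = 4, replicates = 3,
                         noise = noiseless(), seed = 5,
                         exWavelengths = ex, emWavelengths = em)
  expect_identical(intensities(p1[[1]]), intensities(p1[[2]]))
  expect_identical(intensities(p1[[1]]), intensities(p1[[3]]))
  expect_error(calibrationPanel("ATO", levels = numeric(0)), "empty")
  # same master seed reproduces the panel bit for bit
  q <- calibrationPanel("ATO", levels = c(0.4, 2, 6), replicates = 2,
                        noise = defaultNoise(), seed = 5,
                        exWavelengths = ex, emWavelengths = em)
  q2 <- calibrationPanel("ATO", levels = c(0.4, 2, 6), replicates = 2,
                         noise = defaultNoise(), seed = 5,
                         exWavelengths = ex, emWavelengths = em)
  for (i in seq_along(q))
    expect_identical(intensities(q[[i]]), intensities(q2[[i]]))
})

test_that("mixture panels cover the fixed-ratio series and blanks", {
  pairs <- defaultMixturePairs()
  expect_equal(pairs$ATO, c(0.5, 1, 1.5, 2, 2.5))
  expect_equal(pairs$ASP / pairs$ATO, rep(3.75, 5))
  ex <- wavelengthGrid(250, 350, 5); em <- wavelengthGrid(300, 450, 5)
  blank <- mixturePanel(data.frame(ASP = 0, ATO = 0), noise = noiseless(),
                        seed = 1, background = 2,
                        exWavelengths = ex, emWavelengths = em)
  expect_equal(unique(as.vector(intensities(blank[[1]]))), 2)
})

test_that("default noise keeps triplicate mixture quantification in the repeatability band", {
  cfg <- runConfig()
  curves <- noisyCurves()
  rsds <- c()
  for (lev in c(1, 3, 5)) {
    pr <- defaultMixturePairs()[lev, , drop = FALSE]
    reps <- lapply(1:3, function(r)
      mixturePanel(pr, noise = cfg@noise, seed = 40 + 3 * lev + r)[[1]])
    found <- sapply(reps, function(e) analyzeMixture(e, curves, cfg)$found)
    rsds <- c(rsds, 100 * apply(found, 1, sd) / rowMeans(found))
  }
  expect_true(all(rsds <= 2.0))
  expect_gte(mean(rsds), 0.3)
})
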