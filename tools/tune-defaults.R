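#!/usr/bin/env Rscript
# One-off tuning of the package's frozen simulator defaults.
#
# The band maxima (ASP ex 285 / em 405 nm, ATO ex 300 / em 364 nm) are
# fixed; band widths, relative brightness and the noise CV are free
# modelling choices. This script documents how the frozen values in
# defaultModels()/defaultNoise() were selected. It was run once; the
# results are frozen in R/fluorophores.R and are not re-derived at build
# or test time.
#
# Width selection (closed form).  For a separable Gaussian fluorophore
# the synchronous trace at offset D is a Gaussian peaking at the
# precision-weighted mean  ((exMax + D)/sx^2 + emMax/sm^2) / (1/sx^2 + 1/sm^2).
# Each pure analyte's first-derivative zero crossing sits at that peak,
# and the crossing is the other analyte's measurement wavelength.  We
# grid-search widths so that at D = 80 nm the crossings land near the
# literature anchors (ASP crossing ~384 nm -> ATO channel; ATO crossing
# ~365 nm -> ASP channel) and check that the scored delta-lambda scan
# over 20-120 nm peaks within +/-10 nm of 80.
#
# Brightness ratio.  The worst-case replicate RSD of a mixture panel is
# set by the ratio of the co-analyte's local intensity (driving the
# proportional noise reaching the derivative) to the analyte's own
# derivative sensitivity.  Brightness ASP:ATO = 100:150 approximately
# balances that worst case across the two channels on the fixed-ratio
# (1:3.75) mixture series.
#
# Noise CV.  With the widths and brightness frozen, the proportional CV
# is chosen so that triplicate quantification of mixture levels shows a
# percent RSD comfortably inside the 0.3-2.0% band that brackets
# bench-instrument repeatability for this assay (~1.2-1.4%), with enough
# margin that the chi-square spread of a 3-replicate SD estimate stays
# below 2% at any seed.

suppressMessages(library(syncfluor))

syncPeak <- function(exMax, emMax, sx, sm, D)
  ((exMax + D) / sx^2 + emMax / sm^2) / (1 / sx^2 + 1 / sm^2)

cat("== width grid search (anchors 384 / 365 nm at delta-lambda 80) ==\n")
best <- NULL
for (sxA in seq(24, 32, 2)) for (smA in seq(26, 34, 2))      # ASP
  for (sxT in seq(40, 70, 10)) for (smT in seq(14, 22, 2)) { # ATO
    crossASP <- syncPeak(285, 405, sxA, smA, 80)  # -> ATO channel
    crossATO <- syncPeak(300, 364, sxT, smT, 80)  # -> ASP channel
    err <- abs(crossASP - 384) + abs(crossATO - 365)
    if (is.null(best) || err < best$err)
      best <- list(sxA = sxA, smA = smA, sxT = sxT, smT = smT,
                   crossASP = crossASP, crossATO = crossATO, err = err)
  }
print(unlist(best))
# frozen: ASP 28 / 29.4, ATO 60 / 17 — an off-grid fine-tune with the
# same anchor error as the coarse-grid winner (crossings 384.03 / 365.19),
# preferring the narrower, more band-like widths.

cat("\n== scan check on the frozen models ==\n")
cfg <- runConfig(noise = noiseModel(0, 0))
m <- defaultModels()
panels <- lapply(stats::setNames(names(m), names(m)), function(a)
  calibrationPanel(a, cfg@calibrationLevels[[a]][c(1, 3, 6)], replicates = 1,
                   noise = noiseModel(0, 0), seed = 1, models = m))
scan <- scanDeltaLambda(panels, seq(20, 120, 10), cfg)
cat("best delta-lambda:", scan$best, "nm (accept within 80 +/- 10)\n")

cat("\n== noise CV calibration (mixture triplicates) ==\n")
curves <- calibrateChannels(
  lapply(stats::setNames(names(m), names(m)), function(a)
    calibrationPanel(a, cfg@calibrationLevels[[a]], replicates = 1,
                     noise = noiseModel(0, 0), seed = 1, models = m)), cfg)
for (cv in c(0.001, 0.002, 0.004, 0.008)) {
  nm <- noiseModel(additiveSd = 0.1, proportionalCv = cv)
  rsds <- c()
  for (seed in c(3, 17, 71)) for (lev in seq_len(5)) {
    pr <- defaultMixturePairs()[lev, , drop = FALSE]
    reps <- lapply(1:3, function(r)
      mixturePanel(pr, noise = nm, seed = seed * 100 + r)[[1]])
    found <- sapply(reps, function(e) analyzeMixture(e, curves, cfg)$found)
    rsds <- c(rsds, 100 * apply(found, 1, sd) / rowMeans(found))
  }
  cat(sprintf("cv %.3f: mean %%RSD %.3f, max %.3f\n", cv, mean(rsds), max(rsds)))
}
# frozen: additiveSd 0.1, proportionalCv 0.002 (mean ~0.5-0.7%, max well
# below the 2% ceiling)
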