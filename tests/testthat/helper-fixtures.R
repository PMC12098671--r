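# shared fixtures, built once per session and memoised

noiseless <- function() noiseModel(0, 0)

quietConfig <- function(...) runConfig(noise = noiseless(), ...)

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, value) {
  if (!exists(key, envir = .fixtureCache)) assign(key, value, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# noiseless single-replicate pure panels at the default calibration levels
purePanelsNoiseless <- function() memo("purePanels", {
  cfg <- quietConfig()
  m <- defaultModels()
  lapply(stats::setNames(names(m), names(m)), function(a)
    calibrationPanel(a, cfg@calibrationLevels[[a]], replicates = 1,
                     noise = noiseless(), seed = 1, models = m))
})

noiselessCurves <- function() memo("curves", {
  calibrateChannels(purePanelsNoiseless(), quietConfig())
})

# triplicate panels under the default noise model, and their calibration
noisyCurves <- function() memo("noisyCurves", {
  cfg <- runConfig()
  m <- defaultModels()
  panels <- lapply(stats::setNames(names(m), names(m)), function(a)
    calibrationPanel(a, cfg@calibrationLevels[[a]], replicates = 3,
                     noise = cfg@noise, seed = 7, models = m))
  calibrateChannels(panels, cfg)
})

# derivative of a single-fluorophore noiseless EEM at delta-lambda dl
pureDeriv <- function(model, conc, dl = 80, interval = 15) {
  eem <- simulateEEM(list(model), conc, noise = noiseless())
  firstDerivative(synchronousSpectrum(eem, dl), interval)
}
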