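# a lighter configuration so the end-to-end runs stay quick: coarser scan
# axes, fewer calibration levels/replicates
demoConfigYaml <- function(path) {
  writeLines(c(
    "replicates: 2",
    "calibration_levels:",
    "  ATO: [0.4, 1.5, 2.6, 3.7, 6]",
    "  ASP: [1, 3, 5, 7.5, 10]",
    "ex_grid: {start: 220, stop: 500, step: 2}",
    "em_grid: {start: 250, stop: 600, step: 2}"), path)
  path
}

test_that("the demo run writes a complete, deterministic artifact set", {
  cfgPath <- demoConfigYaml(withr::local_tempfile(fileext = ".yaml"))
  cfg <- loadConfig(cfgPath)
  out1 <- withr::local_tempdir()
  man <- runDemo(seed = 7, outDir = out1, config = cfg)
  files <- unlist(man$artifacts)
  expect_gte(length(files), 6)
  expect_true(all(file.exists(files)))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  # mixture recoveries of the demo land inside the acceptance band
  mix <- read.csv(file.path(out1, "mixture-recoveries.csv"), comment.char = "#")
  expect_true(all(mix$percent_recovery >= 98 & mix$percent_recovery <= 102))
  # a second run with the same seed is numerically identical
  out2 <- withr::local_tempdir()
  runDemo(seed = 7, outDir = out2, config = cfg)
  for (f in list.files(out1, pattern = "\\.csv$")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
})

test_that("the CLI maps outcomes onto its documented exit codes", {
  expect_equal(cliMain("--help"), 0L)
  expect_equal(suppressMessages(cliMain("frobnicate")), 1L)
  expect_equal(suppressMessages(cliMain(c("scan", "--seed"))), 1L)
  # validate with a missing calibration file is a data error naming it
  msgs <- capture.output(
    code <- cliMain(c("validate", "--calibration", "no-such-file.csv")),
    type = "message")
  expect_equal(code, 2L)
  expect_match(paste(msgs, collapse = " "), "no-such-file.csv")
  # std-add runs standalone and writes its record
  out <- withr::local_tempdir()
  code <- suppressMessages(
    cliMain(c("std-add", "--base", "75.21", "--added", "7.5",
              "--total", "82.847", "--out-dir", out)))
  expect_equal(code, 0L)
  rec <- read.csv(file.path(out, "standard-addition.csv"), comment.char = "#")
  expect_equal(rec$pure_found, 7.637)
})

test_that("calibrate and quantify cooperate across CLI invocations", {
  cfgPath <- demoConfigYaml(withr::local_tempfile(fileext = ".yaml"))
  out <- withr::local_tempdir()
  expect_equal(suppressMessages(
    cliMain(c("calibrate", "--seed", "3", "--out-dir", out,
              "--config", cfgPath))), 0L)
  calPath <- file.path(out, "calibration.csv")
  expect_true(file.exists(calPath))
  curves <- readCalibrationCsv(calPath)
  expect_setequal(names(curves), c("ASP", "ATO"))
  # write one mixture EEM and quantify it from files
  cfg <- loadConfig(cfgPath)
  eem <- mixturePanel(data.frame(ASP = 3.75, ATO = 1), noise = cfg@noise,
                      seed = 4, exWavelengths = cfg@exGrid,
                      emWavelengths = cfg@emGrid)[[1]]
  eemPath <- file.path(out, "mix.csv")
  writeEEMCsv(eem, eemPath)
  expect_equal(suppressMessages(
    cliMain(c("quantify", "--calibration", calPath, "--eem", eemPath,
              "--out-dir", out, "--config", cfgPath))), 0L)
  q <- read.csv(file.path(out, "quantification.csv"), comment.char = "#")
  expect_equal(q$found[q$analyte == "ATO"], 1, tolerance = 0.02)
  expect_equal(q$found[q$analyte == "ASP"], 3.75, tolerance = 0.02)
})
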