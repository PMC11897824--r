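test_that("simulated lamp spectra are positive, smooth and seed-deterministic", {
  grid <- seq(450, 650, 1)
  l1 <- makeLampSpectrum(grid, seed = 5)
  l2 <- makeLampSpectrum(grid, seed = 5)
  l3 <- makeLampSpectrum(grid, seed = 6)
  expect_true(all(specValues(l1) > 0))
  expect_identical(specValues(l1), specValues(l2))
  expect_false(identical(specValues(l1), specValues(l3)))
  expect_error(makeLampSpectrum(numeric(0)), class = "spx_parameter_error")

  # the lamp is far smoother than the haemoglobin bands: compare peak
  # normalized curvature against the extinction table on the same grid
  curv <- function(v) max(abs(diff(v, differences = 2))) / max(v)
  eps <- resampleExtinction(hbTab, grid)
  expect_lt(curv(specValues(l1)), 0.1 * curv(epsHbO2(eps)))
})

test_that("reflectance synthesis inverts to the truth and respects feasibility", {
  lamp <- makeLampSpectrum(seq(498, 602), seed = 1)
  # zero truth, zero noise: measured is the lamp
  m0 <- makeReflectance(0, 0, numeric(0), lamp, extinction = hbTab)
  expect_equal(specValues(m0), specValues(lamp))

  # infeasible truth: absorbance exceeding the lamp
  expect_error(makeReflectance(1, 1, numeric(0), lamp, extinction = hbTab),
               class = "spx_infeasible_error")

  # end-to-end: pipeline StO2 equals the constructed truth
  m <- makeReflectance(0.7 * 4e-6, 0.3 * 4e-6, c(0.03, -0.01, 0.002), lamp,
                       extinction = hbTab)
  f <- fitAbsorption(inferAbsorption(m, lamp, anchorScale = FALSE), hbTab)
  expect_equal(sto2(f), 0.7, tolerance = 1e-3)
})

test_that("scenario truth profiles follow their scenario definitions", {
  ctrl <- makeScenario(scenarioConfigNew("control", durationS = 300,
                                         noiseFrac = 0))
  expect_true(all(trueSto2(ctrl) == 0.95))

  rej <- makeScenario(scenarioConfigNew("rejection", durationS = 3600,
                                        eventTimeS = 1800, noiseFrac = 0))
  ts <- trueSto2(rej); tt <- sampleTimes(rej)
  expect_true(all(ts[tt <= 1800] == 0.95))
  expect_equal(ts[tt >= 2100][1], 0.95 - 0.12)
  expect_true(all(diff(ts) <= 1e-12))

  thr <- makeScenario(scenarioConfigNew("thrombosis", durationS = 750,
                                        noiseFrac = 0))
  expect_true(all(diff(trueSto2(thr)) <= 1e-12))
  # plateau below the threshold flow: the 25% and 0% stages share one StO2
  fl <- thr@flowPct
  expect_equal(unique(trueSto2(thr)[fl <= 25]),
               0.95 - scenarioConfig(thr)@eventMagnitude)
})

test_that("identical configs give bit-identical scenarios", {
  cfg <- scenarioConfigNew("haemorrhage", durationS = 600, eventTimeS = 300,
                           seed = 17)
  a <- makeScenario(cfg)
  b <- makeScenario(cfg)
  expect_identical(lapply(scenarioSpectra(a), specValues),
                   lapply(scenarioSpectra(b), specValues))
  expect_identical(rbfi(rbfi(a)), rbfi(rbfi(b)))
})

test_that("noiseless pipelines recover the truth for every scenario kind", {
  for (kind in c("control", "rejection", "thrombosis", "haemorrhage")) {
    cfg <- scenarioConfigNew(kind, durationS = 600, sampleIntervalS = 60,
                             eventTimeS = 300, noiseFrac = 0, seed = 2)
    truth <- makeScenario(cfg)
    est <- pipelineSto2(truth)
    expect_lt(max(abs(est - trueSto2(truth))), 1e-3)
  }
})

test_that("artifact injection corrupts spectra but never the truth", {
  cfg <- scenarioConfigNew("control", durationS = 300, sampleIntervalS = 60,
                           noiseFrac = 0, seed = 9)
  base <- makeScenario(cfg)

  zero <- injectArtifact(base, "ambient-light", atS = 120, magnitude = 0)
  expect_identical(lapply(scenarioSpectra(zero), specValues),
                   lapply(scenarioSpectra(base), specValues))

  amb <- injectArtifact(base, "ambient-light", atS = 120, magnitude = 0.2)
  expect_identical(trueSto2(amb), trueSto2(base))
  ref <- referenceSpectrum(amb)
  flags <- vapply(seq_along(sampleTimes(amb)), function(i)
    flagQuality(scenarioSpectra(amb)[[i]], ref), character(1))
  hit <- sampleTimes(amb) >= 120
  expect_true(all(flags[hit] == "ambient-light"))
  expect_true(all(flags[!hit] == "ok"))

  # 50% coupling loss against a 25% slip threshold: transition flagged
  slip <- injectArtifact(base, "probe-slip", atS = 120, magnitude = 0.5)
  i0 <- which(sampleTimes(slip) >= 120)[1]
  expect_identical(
    flagQuality(scenarioSpectra(slip)[[i0]], ref,
                previous = scenarioSpectra(slip)[[i0 - 1]]),
    "probe-slip")

  expect_error(injectArtifact(base, "ambient-light", atS = 1e6,
                              magnitude = 0.1),
               class = "spx_parameter_error")
})

test_that("scenario files round-trip through the writer", {
  dir <- withr::local_tempdir()
  cfg <- scenarioConfigNew("control", durationS = 120, sampleIntervalS = 60,
                           seed = 3)
  truth <- makeScenario(cfg)
  writeScenario(truth, dir)
  expect_true(file.exists(file.path(dir, "reference.csv")))
  expect_length(list.files(dir, pattern = "^sample_"), 3)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$true_sto2, trueSto2(truth))
  back <- readSpectrum(file.path(dir, "sample_0001.csv"), "reflectance")
  expect_equal(specValues(back), specValues(scenarioSpectra(truth)[[1]]),
               tolerance = 1e-6)
})
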