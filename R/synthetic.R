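## All simulator randomness flows from one master seed through mixSeed(),
## so every sample's draws are independent of how many other draws happened
## before it (adding an artifact never perturbs pre-existing draws).
mixSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729 + 1) %%
               2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a ScenarioConfig
#'
#' Scenario-kind defaults mirror the perfusion experiments the simulator
#' emulates: continuous acquisition every 15 s; rejection decompensates
#' ~35 min after the intervention; thrombosis steps the pump flow
#' 100/75/50/25/0% at equal intervals with StO2 declining linearly with
#' flow until the 25% perfusion-threshold then plateauing; haemorrhage is an
#' abrupt synchronized StO2 + flow-index drop late in the run.
#'
#' @param scenario `"rejection"`, `"thrombosis"`, `"haemorrhage"` or
#'   `"control"`.
#' @param durationS run duration, s.
#' @param sampleIntervalS acquisition spacing, s (default 15).
#' @param baselineSto2 true baseline saturation (default 0.95).
#' @param eventTimeS event onset, s (defaults: rejection 2100 s after a
#'   nominal intervention at 0, i.e. mid-run; haemorrhage 6300 s).
#' @param eventMagnitude StO2 drop (defaults: rejection 0.12, haemorrhage
#'   0.03, otherwise 0).
#' @param eventRampS ramp length over which an "abrupt" event unfolds, s
#'   (default 300).
#' @param rbfiBaseline baseline flow index, arbitrary units (default 100).
#' @param noiseFrac sd of multiplicative intensity noise (default 0.01).
#' @param amplitudeFrac peak of the true haemoglobin absorbance relative to
#'   the lamp (default 0.5: perfused tissue absorbs strongly in the
#'   haemoglobin window).
#' @param thresholdFlowPct thrombosis perfusion-threshold flow (default 25).
#' @param seed integer master seed.
#' @return A validated [ScenarioConfig-class].
#' @export
scenarioConfigNew <- function(scenario = "control",
                              durationS = if (scenario == "haemorrhage")
                                7200 else 3600,
                              sampleIntervalS = 15,
                              baselineSto2 = 0.95,
                              eventTimeS = switch(scenario,
                                rejection = 2100, haemorrhage = 6300, 0),
                              eventMagnitude = switch(scenario,
                                rejection = 0.12, haemorrhage = 0.03,
                                thrombosis = 0.25, 0),
                              eventRampS = 300,
                              rbfiBaseline = 100,
                              noiseFrac = 0.01,
                              amplitudeFrac = 0.5,
                              thresholdFlowPct = 25,
                              seed = 1L) {
  new("ScenarioConfig", scenario = scenario, durationS = durationS,
      sampleIntervalS = sampleIntervalS, baselineSto2 = baselineSto2,
      eventTimeS = eventTimeS, eventMagnitude = eventMagnitude,
      eventRampS = eventRampS, rbfiBaseline = rbfiBaseline,
      noiseFrac = noiseFrac, amplitudeFrac = amplitudeFrac,
      thresholdFlowPct = thresholdFlowPct, seed = as.integer(seed))
}

#' Simulate a broadband lamp (reference) spectrum
#'
#' A thermal-emitter (Planck, ~3200 K) curve -- slowly rising toward long
#' wavelengths across 500--600 nm -- times a gentle seeded long-period
#' ripple emulating fibre/grating transmission structure. Strictly positive,
#' smooth (its curvature is far below the haemoglobin bands'), and
#' deterministic given the seed.
#'
#' @param grid wavelengths, nm, within 400--1000.
#' @param seed integer seed.
#' @param peakCounts approximate peak intensity in counts (default 40000).
#' @return A reference [Spectrum-class].
#' @export
makeLampSpectrum <- function(grid, seed = 1L, peakCounts = 40000) {
  grid <- as.numeric(grid)
  if (length(grid) == 0L)
    spxStop("spx_parameter_error", "empty wavelength grid")
  wv <- validWavelengths(grid)
  if (is.character(wv)) spxStop("spx_parameter_error", "grid: %s", wv)
  planck <- grid^-5 / (exp(1.4388e7 / (grid * 3200)) - 1)
  base <- planck / max(planck)
  ripple <- withSeed(mixSeed(seed, 0L), {
    ph <- stats::runif(2, 0, 2 * pi)
    0.02 * cos(2 * pi * grid / 400 + ph[1]) +
      0.01 * cos(2 * pi * grid / 250 + ph[2])
  })
  Spectrum(grid, peakCounts * base * (1 + ripple), kind = "reference")
}

#' Simulate a reflectance spectrum from known truth
#'
#' Exact inverse of the package's absolute-difference absorption inference:
#' `measured = lamp - A*`, where `A*` is [evaluateModel()] evaluated at the
#' true amplitudes and background, then multiplied by `(1 + e)` with
#' `e ~ N(0, noiseFrac)` per wavelength and clipped at zero. With zero noise
#' and anchor scaling disabled, [inferAbsorption()] recovers `A*` exactly.
#'
#' @param aHbO2,aHb true amplitudes.
#' @param background true background coefficients (in the centred scaled
#'   coordinate of `window`).
#' @param lamp the lamp [Spectrum-class].
#' @param noiseFrac multiplicative noise sd.
#' @param seed integer seed.
#' @param extinction [ExtinctionTable-class] (default: bundled table).
#' @param window window whose centre anchors the background coordinate.
#' @return A reflectance [Spectrum-class] on the lamp's grid.
#' @section Errors: `spx_infeasible_error` when the truth absorbance
#'   exceeds the lamp anywhere.
#' @export
makeReflectance <- function(aHbO2, aHb, background, lamp, noiseFrac = 0,
                            seed = 1L,
                            extinction = loadExtinctionTable(),
                            window = HB_WINDOW_NM) {
  stopifnot(is(lamp, "Spectrum"))
  astar <- evaluateModel(aHbO2, aHb, background, extinction,
                         lamp@wavelength, lambdaC = mean(window))
  clean <- lamp@values - astar@values
  if (any(clean < 0))
    spxStop("spx_infeasible_error",
            "truth absorbance exceeds the lamp (max A* = %.3g, min lamp = %.3g)",
            max(astar@values), min(lamp@values))
  vals <- if (noiseFrac > 0) {
    noisy <- withSeed(seed,
                      clean * (1 + stats::rnorm(length(clean), 0, noiseFrac)))
    pmax(noisy, 0)
  } else clean
  Spectrum(lamp@wavelength, vals, kind = "reflectance")
}

## True StO2 profile over `times` for a scenario config.
scenarioTruthProfile <- function(config, times) {
  b <- config@baselineSto2
  switch(config@scenario,
    control = rep(b, length(times)),
    rejection = ,
    haemorrhage = {
      frac <- pmin(pmax((times - config@eventTimeS) / config@eventRampS, 0), 1)
      b - config@eventMagnitude * frac
    },
    thrombosis = {
      flow <- thrombosisFlow(config, times)
      thr <- config@thresholdFlowPct
      b - config@eventMagnitude * (100 - pmax(flow, thr)) / (100 - thr)
    })
}

## Pump flow percent per sample for the thrombosis scenario: equal-length
## stages at 100/75/50/25/0%.
thrombosisFlow <- function(config, times) {
  levels <- c(100, 75, 50, 25, 0)
  stage <- pmin(floor(times / (config@durationS / length(levels))) + 1,
                length(levels))
  levels[stage]
}

scenarioRbfi <- function(config, times) {
  base <- config@rbfiBaseline
  clean <- switch(config@scenario,
    control = rep(base, length(times)),
    rejection = ,
    haemorrhage = {
      frac <- pmin(pmax((times - config@eventTimeS) / config@eventRampS, 0), 1)
      base * (1 - 0.95 * frac)  # collapse to 5% of baseline
    },
    thrombosis = base * thrombosisFlow(config, times) / 100)
  noise <- if (config@noiseFrac > 0)
    withSeed(mixSeed(config@seed, 1L),
             stats::rnorm(length(times), 0, config@noiseFrac)) else 0
  pmax(clean * (1 + noise), 0)
}

#' Simulate a full perfusion scenario with ground truth
#'
#' Generates a lamp spectrum, a per-sample true StO2 course, a coupled
#' flow-index series and one reflectance spectrum per sample via
#' [makeReflectance()]. Total haemoglobin is held constant across the run
#' (only the oxygenated fraction changes); its amplitude is scaled so that
#' the peak true absorbance is `amplitudeFrac` of the lamp, with a small
#' fixed quadratic background included in the truth. All randomness derives
#' from `config@seed` through a documented per-sample derivation
#' (sample `i` uses sub-seed `mixSeed(seed, 10 + i)`), so outputs are
#' bit-identical for identical configs.
#'
#' @param config a [ScenarioConfig-class] (see [scenarioConfigNew()]).
#' @param extinction [ExtinctionTable-class] used as forward-model truth.
#' @param grid wavelength grid of the simulated spectra (default
#'   `seq(498, 602)` nm, 1 nm spacing).
#' @return A [ScenarioTruth-class].
#' @export
makeScenario <- function(config, extinction = loadExtinctionTable(),
                         grid = seq(498, 602, by = 1)) {
  stopifnot(is(config, "ScenarioConfig"))
  validObject(config)
  times <- seq(0, config@durationS, by = config@sampleIntervalS)
  lamp <- makeLampSpectrum(grid, seed = config@seed)
  trueS <- scenarioTruthProfile(config, times)
  eps <- resampleExtinction(extinction, grid)
  inWin <- grid >= HB_WINDOW_NM[1] & grid <= HB_WINDOW_NM[2]
  epsMax <- pmax(eps@epsHbO2, eps@epsHb)
  # constant total haemoglobin amplitude: worst case over StO2 stays feasible
  aTot <- 0.9 * config@amplitudeFrac *
    min(lamp@values[inWin] / epsMax[inWin])
  # small smooth background, a fixed fraction of the haemoglobin signal
  refA <- aTot * max(epsMax[inWin])
  bg <- refA * c(0.05, -0.01, 0.004)
  spectra <- vector("list", length(times))
  for (i in seq_along(times)) {
    spectra[[i]] <- makeReflectance(
      aHbO2 = trueS[i] * aTot, aHb = (1 - trueS[i]) * aTot,
      background = bg, lamp = lamp, noiseFrac = config@noiseFrac,
      seed = mixSeed(config@seed, 10L + i), extinction = extinction)
    spectra[[i]]@meta <- list(timestamp_s = times[i],
                              integration_s = config@sampleIntervalS)
  }
  flow <- if (config@scenario == "thrombosis")
    thrombosisFlow(config, times) else rep(NA_real_, length(times))
  new("ScenarioTruth", config = config, times = times, trueSto2 = trueS,
      flowPct = flow, rbfi = RBFiSeries(times, scenarioRbfi(config, times)),
      reference = lamp, spectra = spectra)
}

#' Inject an acquisition artifact into simulated spectra
#'
#' Corrupts the reflectance spectra from `atS` onward; the truth series is
#' never modified (artifacts corrupt measurements, not physiology).
#' `"ambient-light"` adds a broadband positive offset of
#' `magnitude * max(lamp)` (stray room light); `"probe-slip"` multiplies the
#' probe coupling by `(1 - magnitude)`.
#'
#' @param truth a [ScenarioTruth-class].
#' @param artifact `"ambient-light"` or `"probe-slip"`.
#' @param atS onset time, s, within the run.
#' @param magnitude artifact magnitude, fraction.
#' @param seed unused at present (artifact shapes are deterministic); kept
#'   so callers can pin a derivation slot for future stochastic artifacts.
#' @return The modified [ScenarioTruth-class], with the artifact logged in
#'   its `artifacts` slot.
#' @export
injectArtifact <- function(truth, artifact = c("ambient-light", "probe-slip"),
                           atS, magnitude, seed = 1L) {
  stopifnot(is(truth, "ScenarioTruth"))
  artifact <- match.arg(artifact)
  if (atS < 0 || atS > truth@config@durationS)
    spxStop("spx_parameter_error", "artifact time %g s outside the run", atS)
  if (magnitude < 0)
    spxStop("spx_parameter_error", "magnitude must be >= 0")
  hit <- which(truth@times >= atS)
  lampMax <- max(truth@reference@values)
  for (i in hit) {
    s <- truth@spectra[[i]]
    s@values <- if (artifact == "ambient-light")
      s@values + magnitude * lampMax
    else s@values * (1 - magnitude)
    truth@spectra[[i]] <- s
  }
  truth@artifacts <- rbind(truth@artifacts,
                           data.frame(kind = artifact, at_s = atS,
                                      magnitude = magnitude))
  truth
}

#' Write a simulated scenario to disk
#'
#' Writes `reference.csv`, `sample_NNNN.csv` per acquisition (spectrum CSV
#' dialect), `rbfi.csv` and `truth.json` (config plus true series) into
#' `dir`.
#'
#' @param truth a [ScenarioTruth-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScenario <- function(truth, dir) {
  stopifnot(is(truth, "ScenarioTruth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSpectrum(truth@reference, file.path(dir, "reference.csv"))
  for (i in seq_along(truth@spectra))
    writeSpectrum(truth@spectra[[i]],
                  file.path(dir, sprintf("sample_%04d.csv", i)))
  writeRBFiSeries(truth@rbfi, file.path(dir, "rbfi.csv"))
  cfg <- truth@config
  jsonlite::write_json(
    list(config = list(scenario = cfg@scenario, duration_s = cfg@durationS,
                       sample_interval_s = cfg@sampleIntervalS,
                       baseline_sto2 = cfg@baselineSto2,
                       event_time_s = cfg@eventTimeS,
                       event_magnitude = cfg@eventMagnitude,
                       event_ramp_s = cfg@eventRampS,
                       rbfi_baseline = cfg@rbfiBaseline,
                       noise_frac = cfg@noiseFrac,
                       amplitude_frac = cfg@amplitudeFrac,
                       threshold_flow_pct = cfg@thresholdFlowPct,
                       seed = cfg@seed),
         time_s = truth@times, true_sto2 = truth@trueSto2,
         flow_pct = truth@flowPct,
         artifacts = truth@artifacts),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
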