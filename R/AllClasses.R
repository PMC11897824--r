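#' @import methods
NULL

SPECTRUM_KINDS <- c("reflectance", "reference", "absorbance")
MEASUREMENT_SITES <- c("hilum", "superior", "lateral", "inferior")
QUALITY_FLAGS <- c("ok", "ambient-light", "probe-slip", "fit-failed")
SCENARIO_KINDS <- c("rejection", "thrombosis", "haemorrhage", "control")

## Wavelengths admissible for any spectrum; model fitting is further
## restricted to the haemoglobin window (default 500-600 nm).
WAVELENGTH_SPAN_NM <- c(400, 1000)
HB_WINDOW_NM <- c(500, 600)

validWavelengths <- function(w) {
  if (length(w) == 0L) return("wavelength grid is empty")
  if (anyNA(w)) return("wavelength grid contains NA")
  if (any(diff(w) <= 0)) return("wavelengths must be strictly increasing")
  if (min(w) < WAVELENGTH_SPAN_NM[1] || max(w) > WAVELENGTH_SPAN_NM[2])
    return(sprintf("wavelengths must lie within [%g, %g] nm",
                   WAVELENGTH_SPAN_NM[1], WAVELENGTH_SPAN_NM[2]))
  TRUE
}

#' Spectrum: per-wavelength magnitudes with acquisition metadata
#'
#' A single spectroscopic record on an ordered wavelength grid. `kind`
#' distinguishes raw probe reflectance, the lamp/reference spectrum, and
#' inferred absorbance. Reflectance and reference values are detector counts
#' and must be non-negative; absorbance values are unconstrained in sign.
#'
#' @slot wavelength numeric, strictly increasing wavelengths in nm within
#'   400--1000 nm.
#' @slot values numeric, same length as `wavelength`.
#' @slot kind one of `"reflectance"`, `"reference"`, `"absorbance"`.
#' @slot meta named list of acquisition metadata. Recognised keys:
#'   `timestamp_s` (seconds from perfusion start, negative allowed),
#'   `integration_s` (> 0), `site` (one of hilum/superior/lateral/inferior),
#'   `notes` (free text).
#' @exportClass Spectrum
setClass("Spectrum",
  representation(wavelength = "numeric", values = "numeric",
                 kind = "character", meta = "list"),
  prototype(meta = list()))

setValidity("Spectrum", function(object) {
  msgs <- character()
  wv <- validWavelengths(object@wavelength)
  if (is.character(wv)) msgs <- c(msgs, wv)
  if (length(object@values) != length(object@wavelength))
    msgs <- c(msgs, "values and wavelength differ in length")
  if (length(object@kind) != 1L || !object@kind %in% SPECTRUM_KINDS)
    msgs <- c(msgs, sprintf("kind must be one of %s",
                            paste(SPECTRUM_KINDS, collapse = ", ")))
  else if (object@kind %in% c("reflectance", "reference") &&
           any(object@values < 0, na.rm = TRUE))
    msgs <- c(msgs, sprintf("%s values must be >= 0", object@kind))
  it <- object@meta$integration_s
  if (!is.null(it) && (!is.numeric(it) || it <= 0))
    msgs <- c(msgs, "integration_s must be > 0")
  st <- object@meta$site
  if (!is.null(st) && !st %in% MEASUREMENT_SITES)
    msgs <- c(msgs, sprintf("site must be one of %s",
                            paste(MEASUREMENT_SITES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a Spectrum
#'
#' @param wavelength strictly increasing wavelengths, nm.
#' @param values per-wavelength magnitudes (counts or absorbance units).
#' @param kind `"reflectance"`, `"reference"` or `"absorbance"`.
#' @param meta named list of acquisition metadata (see [Spectrum-class]).
#' @return A validated [Spectrum-class] object.
#' @examples
#' s <- Spectrum(500:600, rep(1000, 101), "reference")
#' @export
Spectrum <- function(wavelength, values, kind = "absorbance", meta = list()) {
  obj <- new("Spectrum", wavelength = as.numeric(wavelength),
             values = as.numeric(values), kind = kind, meta = meta)
  obj
}

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum (%s): %d points, %.1f-%.1f nm\n", object@kind,
              length(object@wavelength), min(object@wavelength),
              max(object@wavelength)))
  if (!is.null(object@meta$site))
    cat("  site:", object@meta$site, "\n")
  if (!is.null(object@meta$timestamp_s))
    cat("  timestamp_s:", object@meta$timestamp_s, "\n")
  invisible(object)
})

#' ExtinctionTable: molar extinction spectra of HbO2 and Hb
#'
#' Wavelength-indexed extinction coefficients (L mol^-1 cm^-1) for oxygenated
#' and deoxygenated haemoglobin. Coefficients must be strictly positive over
#' the 500--600 nm fitting window.
#'
#' @slot wavelength numeric, strictly increasing, nm.
#' @slot epsHbO2 numeric, extinction of oxygenated haemoglobin.
#' @slot epsHb numeric, extinction of deoxygenated haemoglobin.
#' @slot source character scalar recording provenance of the values.
#' @exportClass ExtinctionTable
setClass("ExtinctionTable",
  representation(wavelength = "numeric", epsHbO2 = "numeric",
                 epsHb = "numeric", source = "character"),
  prototype(source = NA_character_))

setValidity("ExtinctionTable", function(object) {
  msgs <- character()
  wv <- validWavelengths(object@wavelength)
  if (is.character(wv)) msgs <- c(msgs, wv)
  if (length(object@epsHbO2) != length(object@wavelength) ||
      length(object@epsHb) != length(object@wavelength))
    msgs <- c(msgs, "coefficient columns must match the wavelength grid")
  inWin <- object@wavelength >= HB_WINDOW_NM[1] &
           object@wavelength <= HB_WINDOW_NM[2]
  if (any(inWin) &&
      (any(object@epsHbO2[inWin] <= 0) || any(object@epsHb[inWin] <= 0)))
    msgs <- c(msgs, "extinction coefficients must be > 0 over 500-600 nm")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ExtinctionTable", function(object) {
  cat(sprintf("ExtinctionTable: %d wavelengths, %.1f-%.1f nm (source: %s)\n",
              length(object@wavelength), min(object@wavelength),
              max(object@wavelength), object@source))
  invisible(object)
})

#' HbFit: result of fitting the haemoglobin absorption model
#'
#' Holds the fitted combined amplitudes a = <L> c ln(10) for each haemoglobin
#' species (uncalibrated: path length and concentration are not separable),
#' the polynomial background coefficients, the derived StO2 and the residual.
#'
#' @slot aHbO2,aHb non-negative fitted amplitudes.
#' @slot background polynomial coefficients b0..bk of the background term,
#'   in the centred scaled coordinate ((lambda - lambdaC) / 50).
#' @slot sto2 saturation fraction in \[0, 1\], or `NA` when both amplitudes
#'   vanish (flag `fit-failed`).
#' @slot rss residual sum of squares (>= 0).
#' @slot converged logical success flag.
#' @slot nPoints number of spectral points used.
#' @slot window fit window in nm.
#' @slot lambdaC centre wavelength of the background coordinate.
#' @exportClass HbFit
setClass("HbFit",
  representation(aHbO2 = "numeric", aHb = "numeric", background = "numeric",
                 sto2 = "numeric", rss = "numeric", converged = "logical",
                 nPoints = "integer", window = "numeric", lambdaC = "numeric"))

setValidity("HbFit", function(object) {
  msgs <- character()
  if (object@aHbO2 < 0 || object@aHb < 0)
    msgs <- c(msgs, "amplitudes must be >= 0")
  if (object@rss < 0) msgs <- c(msgs, "rss must be >= 0")
  if (!is.na(object@sto2) && (object@sto2 < 0 || object@sto2 > 1))
    msgs <- c(msgs, "sto2 must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "HbFit", function(object) {
  cat(sprintf(
    "HbFit: StO2 = %s, aHbO2 = %.4g, aHb = %.4g, rss = %.4g (%s, %d pts)\n",
    if (is.na(object@sto2)) "NA" else sprintf("%.3f", object@sto2),
    object@aHbO2, object@aHb, object@rss,
    if (object@converged) "converged" else "NOT converged", object@nPoints))
  invisible(object)
})

#' StO2Series: timestamped saturation estimates with quality flags
#'
#' @slot times numeric, strictly increasing timestamps in seconds from
#'   perfusion start (negative allowed for pre-perfusion records).
#' @slot sto2 numeric saturation fractions; `NA` allowed where the flag is
#'   not `"ok"`.
#' @slot flags character, one of ok / ambient-light / probe-slip / fit-failed
#'   per sample.
#' @exportClass StO2Series
setClass("StO2Series",
  representation(times = "numeric", sto2 = "numeric", flags = "character"))

setValidity("StO2Series", function(object) {
  msgs <- character()
  n <- length(object@times)
  if (n > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (length(object@sto2) != n || length(object@flags) != n)
    msgs <- c(msgs, "times, sto2 and flags must have equal length")
  else {
    if (!all(object@flags %in% QUALITY_FLAGS))
      msgs <- c(msgs, sprintf("flags must be in {%s}",
                              paste(QUALITY_FLAGS, collapse = ", ")))
    okv <- object@sto2[object@flags == "ok"]
    if (anyNA(okv) || any(okv < 0 | okv > 1))
      msgs <- c(msgs, "sto2 must lie in [0, 1] wherever the flag is ok")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an StO2Series
#' @param times strictly increasing timestamps, s.
#' @param sto2 saturation fractions.
#' @param flags per-sample quality flags (default all `"ok"`).
#' @return A validated [StO2Series-class].
#' @export
StO2Series <- function(times, sto2, flags = rep("ok", length(times))) {
  new("StO2Series", times = as.numeric(times), sto2 = as.numeric(sto2),
      flags = as.character(flags))
}

setMethod("show", "StO2Series", function(object) {
  cat(sprintf("StO2Series: %d samples, t = %.0f..%.0f s; flags: %s\n",
              length(object@times),
              if (length(object@times)) min(object@times) else NA,
              if (length(object@times)) max(object@times) else NA,
              paste(sprintf("%s=%d", names(table(object@flags)),
                            table(object@flags)), collapse = " ")))
  invisible(object)
})

#' RBFiSeries: renal blood flow index time series
#'
#' Flow-index readings from the perfusion circuit, in the rig's arbitrary
#' flow units; only relative changes are interpreted.
#'
#' @slot times numeric, strictly increasing timestamps, s.
#' @slot rbfi numeric, non-negative flow index values.
#' @exportClass RBFiSeries
setClass("RBFiSeries",
  representation(times = "numeric", rbfi = "numeric"))

setValidity("RBFiSeries", function(object) {
  msgs <- character()
  if (length(object@rbfi) != length(object@times))
    msgs <- c(msgs, "times and rbfi must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (any(object@rbfi < 0, na.rm = TRUE))
    msgs <- c(msgs, "rbfi must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct an RBFiSeries
#' @param times strictly increasing timestamps, s.
#' @param rbfi non-negative flow index values.
#' @return A validated [RBFiSeries-class].
#' @export
RBFiSeries <- function(times, rbfi) {
  new("RBFiSeries", times = as.numeric(times), rbfi = as.numeric(rbfi))
}

#' PumpStepdownResult: StO2 response to staged pump-flow reduction
#'
#' @slot flows pump flow levels, percent of full flow, strictly decreasing.
#' @slot sto2 StO2 estimate per level.
#' @slot largestDropInterval the adjacent flow pair (high, low) with the
#'   maximal StO2 decrease.
#' @slot plateauOnset first flow level after which successive StO2 changes
#'   stay below the plateau tolerance through the end (`NA` if none).
#' @slot plateauTol tolerance used for plateau detection.
#' @exportClass PumpStepdownResult
setClass("PumpStepdownResult",
  representation(flows = "numeric", sto2 = "numeric",
                 largestDropInterval = "numeric", plateauOnset = "numeric",
                 plateauTol = "numeric"))

setValidity("PumpStepdownResult", function(object) {
  msgs <- character()
  if (length(object@flows) != length(object@sto2))
    msgs <- c(msgs, "flows and sto2 must have equal length")
  if (length(object@flows) > 1 && any(diff(object@flows) >= 0))
    msgs <- c(msgs, "flows must be strictly decreasing")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PumpStepdownResult", function(object) {
  cat(sprintf(
    "PumpStepdownResult: %d levels; largest drop %g%% -> %g%%; plateau onset %s%%\n",
    length(object@flows), object@largestDropInterval[1],
    object@largestDropInterval[2],
    if (is.na(object@plateauOnset)) "NA" else format(object@plateauOnset)))
  invisible(object)
})

#' EventWindow: detected perfusion event interval
#'
#' @slot start,end window bounds, s (start < end when kind != "none").
#' @slot kind `"decompensation"` or `"none"`.
#' @slot trigger named numeric with the triggering drop magnitudes.
#' @exportClass EventWindow
setClass("EventWindow",
  representation(start = "numeric", end = "numeric", kind = "character",
                 trigger = "numeric"),
  prototype(trigger = c(sto2_drop = NA_real_, rbfi_frac_drop = NA_real_)))

setValidity("EventWindow", function(object) {
  if (!object@kind %in% c("decompensation", "none"))
    return("kind must be 'decompensation' or 'none'")
  if (object@kind != "none" && !(object@start < object@end))
    return("start must be < end")
  TRUE
})

setMethod("show", "EventWindow", function(object) {
  if (object@kind == "none") cat("EventWindow: none detected\n")
  else cat(sprintf("EventWindow: %s, %.0f-%.0f s\n", object@kind,
                   object@start, object@end))
  invisible(object)
})

#' ScenarioConfig: ground-truth description of a simulated perfusion run
#'
#' @slot scenario one of rejection / thrombosis / haemorrhage / control.
#' @slot durationS total duration, s.
#' @slot sampleIntervalS spacing of spectral acquisitions, s (default 15,
#'   matching continuous 15 s acquisition protocols).
#' @slot baselineSto2 true StO2 before any event, fraction.
#' @slot eventTimeS event onset, s from start.
#' @slot eventMagnitude StO2 drop, fraction.
#' @slot eventRampS ramp duration over which an "abrupt" event unfolds, s.
#' @slot rbfiBaseline baseline flow index, arbitrary units.
#' @slot noiseFrac sd of the multiplicative Gaussian intensity noise.
#' @slot amplitudeFrac peak of the true haemoglobin absorbance as a fraction
#'   of the lamp intensity at that wavelength.
#' @slot thresholdFlowPct thrombosis perfusion-threshold flow, percent.
#' @slot seed integer master seed; all randomness derives from it.
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(scenario = "character", durationS = "numeric",
                 sampleIntervalS = "numeric", baselineSto2 = "numeric",
                 eventTimeS = "numeric", eventMagnitude = "numeric",
                 eventRampS = "numeric", rbfiBaseline = "numeric",
                 noiseFrac = "numeric", amplitudeFrac = "numeric",
                 thresholdFlowPct = "numeric", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msgs <- character()
  if (!object@scenario %in% SCENARIO_KINDS)
    msgs <- c(msgs, sprintf("scenario must be one of %s",
                            paste(SCENARIO_KINDS, collapse = ", ")))
  if (object@baselineSto2 < 0 || object@baselineSto2 > 1)
    msgs <- c(msgs, "baselineSto2 must lie in [0, 1]")
  if (object@durationS <= 0) msgs <- c(msgs, "durationS must be > 0")
  if (object@sampleIntervalS <= 0)
    msgs <- c(msgs, "sampleIntervalS must be > 0")
  if (object@scenario %in% c("rejection", "haemorrhage") &&
      (object@eventTimeS < 0 || object@eventTimeS > object@durationS))
    msgs <- c(msgs, "eventTimeS must lie within the duration")
  if (object@noiseFrac < 0) msgs <- c(msgs, "noiseFrac must be >= 0")
  if (object@eventMagnitude < 0 ||
      object@eventMagnitude > object@baselineSto2)
    msgs <- c(msgs, "eventMagnitude must lie in [0, baselineSto2]")
  if (object@amplitudeFrac <= 0 || object@amplitudeFrac > 1)
    msgs <- c(msgs, "amplitudeFrac must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' ScenarioTruth: simulated spectra plus the truth that generated them
#'
#' Applying the analysis pipeline (grid alignment, absorption inference and
#' model fitting) to the noiseless spectra recovers `trueSto2` to better
#' than 1e-3 at every sample; artifacts corrupt only the spectra, never the
#' truth series.
#'
#' @slot config the generating [ScenarioConfig-class].
#' @slot times acquisition timestamps, s.
#' @slot trueSto2 true saturation per sample.
#' @slot flowPct pump flow percent per sample (thrombosis; `NA` otherwise).
#' @slot rbfi [RBFiSeries-class] coupled flow-index series.
#' @slot reference the lamp [Spectrum-class].
#' @slot spectra list of reflectance [Spectrum-class], one per sample.
#' @slot artifacts data.frame log of injected artifacts.
#' @exportClass ScenarioTruth
setClass("ScenarioTruth",
  representation(config = "ScenarioConfig", times = "numeric",
                 trueSto2 = "numeric", flowPct = "numeric",
                 rbfi = "RBFiSeries", reference = "Spectrum",
                 spectra = "list", artifacts = "data.frame"),
  prototype(artifacts = data.frame(kind = character(), at_s = numeric(),
                                   magnitude = numeric())))

setValidity("ScenarioTruth", function(object) {
  n <- length(object@times)
  if (length(object@trueSto2) != n || length(object@spectra) != n)
    return("times, trueSto2 and spectra must have equal length")
  TRUE
})

setMethod("show", "ScenarioTruth", function(object) {
  cat(sprintf("ScenarioTruth (%s): %d samples over %.0f s, seed %d\n",
              object@config@scenario, length(object@times),
              object@config@durationS, object@config@seed))
  invisible(object)
})
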