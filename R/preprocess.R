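#' Quality-flagging thresholds
#'
#' @param ambientExcessFrac flag `ambient-light` when the measured spectrum
#'   exceeds the reference anywhere by more than this fraction (default
#'   0.05): light the lamp did not supply must have entered the probe.
#' @param slipJumpFrac flag `probe-slip` when the summed intensity jumps by
#'   more than this fraction relative to the preceding spectrum (default
#'   0.25): the probe-tissue coupling changed.
#' @param anchorBandNm sub-band used for amplitude matching in
#'   [inferAbsorption()] (default 590--600 nm, the flattest part of the
#'   haemoglobin window).
#' @return A named list of class `"qualityConfig"`.
#' @export
qualityConfig <- function(ambientExcessFrac = 0.05, slipJumpFrac = 0.25,
                          anchorBandNm = c(590, 600)) {
  structure(list(ambientExcessFrac = ambientExcessFrac,
                 slipJumpFrac = slipJumpFrac,
                 anchorBandNm = anchorBandNm),
            class = "qualityConfig")
}

#' Infer an absorption spectrum from reflectance and reference spectra
#'
#' Under the working assumption that probe light not reflected back into the
#' fibre was absorbed by the tissue, the default `"absolute-difference"`
#' method takes the absolute difference between the (amplitude-matched)
#' reference and the measured reflectance. The `"log-ratio"` variant returns
#' `log10(reference / measured)`, i.e. a Beer-Lambert attenuation, and is
#' provided because a bare intensity difference is not an absorbance in
#' Beer-Lambert units; estimates from either route are uncalibrated.
#'
#' Amplitude matching: before differencing, the reference is scaled by the
#' ratio of measured to reference intensity averaged over `anchorBandNm`, so
#' that the difference captures spectral shape rather than lamp/probe
#' coupling efficiency (hand-held probes couple variably). Set
#' `anchorScale = FALSE` to use the raw reference (scale factor 1).
#'
#' @param measured a reflectance [Spectrum-class].
#' @param reference the lamp/reference [Spectrum-class].
#' @param method `"absolute-difference"` (default) or `"log-ratio"`.
#' @param window fit window, nm; the output is restricted to it.
#' @param anchorScale logical, apply anchor-band amplitude matching
#'   (default `TRUE`; absolute-difference only).
#' @param anchorBandNm anchor sub-band, nm (default 590--600).
#' @param toleranceNm grid-alignment tolerance passed to [alignGrids()].
#' @return An absorbance [Spectrum-class] on the common grid restricted to
#'   `window`; metadata is carried over from `measured` plus keys recording
#'   the method and anchor scale factor.
#' @section Errors: `spx_alignment_error` for misaligned/non-overlapping
#'   grids; `spx_domain_error` when log-ratio meets non-positive intensities
#'   after clipping (the clip floor is `1e-6 * max(reference)`).
#' @examples
#' lamp <- Spectrum(500:600, rep(1000, 101), "reference")
#' meas <- Spectrum(500:600, rep(900, 101), "reflectance")
#' a <- inferAbsorption(meas, lamp, anchorScale = FALSE)
#' @export
inferAbsorption <- function(measured, reference,
                            method = c("absolute-difference", "log-ratio"),
                            window = HB_WINDOW_NM, anchorScale = TRUE,
                            anchorBandNm = c(590, 600), toleranceNm = 0.5) {
  method <- match.arg(method)
  stopifnot(is(measured, "Spectrum"), is(reference, "Spectrum"))
  al <- alignGrids(measured, reference, toleranceNm = toleranceNm,
                   window = window)
  grid <- al$a@wavelength
  keep <- grid >= window[1] & grid <= window[2]
  w <- grid[keep]
  m <- al$a@values[keep]
  r <- al$b@values[keep]
  meta <- measured@meta
  meta$method <- method
  if (method == "absolute-difference") {
    scale <- 1
    if (isTRUE(anchorScale)) {
      band <- w >= anchorBandNm[1] & w <= anchorBandNm[2]
      if (!any(band))
        spxStop("spx_parameter_error",
                "anchor band [%g, %g] nm holds no grid points",
                anchorBandNm[1], anchorBandNm[2])
      if (mean(r[band]) <= 0)
        spxStop("spx_domain_error", "reference is non-positive in anchor band")
      scale <- mean(m[band]) / mean(r[band])
    }
    meta$anchor_scale <- scale
    vals <- abs(r * scale - m)
  } else {
    clip <- 1e-6 * max(r)
    meta$clip_floor <- clip
    if (any(r <= 0))
      spxStop("spx_domain_error",
              "log-ratio requires a strictly positive reference")
    vals <- log10(r / pmax(m, clip))
  }
  Spectrum(w, vals, kind = "absorbance", meta = meta)
}

#' Normalize a spectrum to unit maximum
#'
#' Divides all values by the maximum over the 500--600 nm window (used for
#' display of stacked spectra).
#'
#' @param s a [Spectrum-class] with at least one strictly positive value in
#'   the window.
#' @param window window over which the maximum is taken, nm.
#' @return The spectrum scaled so its maximum over `window` is 1.
#' @section Errors: `spx_normalization_error` when no value is positive.
#' @export
normalizeSpectrum <- function(s, window = HB_WINDOW_NM) {
  stopifnot(is(s, "Spectrum"))
  inWin <- s@wavelength >= window[1] & s@wavelength <= window[2]
  if (!any(inWin))
    spxStop("spx_range_error", "spectrum does not cover [%g, %g] nm",
            window[1], window[2])
  mx <- max(s@values[inWin])
  if (!is.finite(mx) || mx <= 0)
    spxStop("spx_normalization_error",
            "spectrum has no strictly positive value to normalize by")
  Spectrum(s@wavelength, s@values / mx, kind = s@kind, meta = s@meta)
}

#' Flag the quality of a measured spectrum
#'
#' Returns a single flag: `"ambient-light"` if the measured spectrum exceeds
#' the reference anywhere by more than `ambientExcessFrac` (stray light was
#' added that the lamp did not supply); otherwise `"probe-slip"` if the total
#' intensity jumped by more than `slipJumpFrac` relative to the preceding
#' spectrum (`previous`); otherwise `"ok"`. The `"fit-failed"` flag is
#' reserved for the fitting stage and never returned here.
#'
#' @param s measured reflectance [Spectrum-class].
#' @param reference lamp [Spectrum-class] (grid-aligned with `s`).
#' @param previous the preceding accepted reflectance spectrum, or `NULL`
#'   when there is no history.
#' @param config a [qualityConfig()].
#' @return One of `"ok"`, `"ambient-light"`, `"probe-slip"`.
#' @export
flagQuality <- function(s, reference, previous = NULL,
                        config = qualityConfig()) {
  stopifnot(is(s, "Spectrum"), is(reference, "Spectrum"))
  al <- alignGrids(s, reference)
  if (any(al$a@values > al$b@values * (1 + config$ambientExcessFrac)))
    return("ambient-light")
  if (!is.null(previous)) {
    stopifnot(is(previous, "Spectrum"))
    tot <- sum(al$a@values)
    alp <- alignGrids(previous, reference)
    prevTot <- sum(alp$a@values)
    if (prevTot > 0 && abs(tot - prevTot) / prevTot > config$slipJumpFrac)
      return("probe-slip")
  }
  "ok"
}
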