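#' Round half away from zero
#'
#' Decimal rounding in which exact halves move away from zero (0.6745 at
#' 3 digits -> 0.675; 92.5 at 0 digits -> 93), the convention used for all
#' reported StO2 values in this package. Base R's `round()` rounds half to
#' even instead.
#'
#' @param x numeric.
#' @param digits number of decimal places.
#' @return `x` rounded.
#' @export
roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Average StO2 over measurement sites
#'
#' Arithmetic mean of the per-site StO2 values of one acquisition row
#' (1--4 of hilum/superior/lateral/inferior present), rounded to 3 decimals
#' half-away-from-zero for reporting.
#'
#' @param row named numeric of site StO2 fractions; names must be site
#'   labels.
#' @return Mean saturation fraction, rounded to 3 decimals.
#' @examples
#' aggregateSites(c(hilum = 0.834, superior = 0.804,
#'                  lateral = 0.635, inferior = 0.426))
#' @export
aggregateSites <- function(row) {
  row <- row[!is.na(row)]
  if (length(row) < 1L)
    spxStop("spx_parameter_error", "at least one site value is required")
  if (!is.null(names(row)) && !all(names(row) %in% MEASUREMENT_SITES))
    spxStop("spx_validation_error", "unknown site label(s): %s",
            paste(setdiff(names(row), MEASUREMENT_SITES), collapse = ", "))
  if (any(row < 0 | row > 1))
    spxStop("spx_validation_error", "site StO2 values must lie in [0, 1]")
  roundHalfAway(mean(row), 3)
}

#' Build a wide site table with per-row averages
#'
#' Pivots a long `time_s,site,sto2` table (see [readSiteTable()]) into one
#' row per acquisition time with one column per site and an `average`
#' column computed by [aggregateSites()].
#'
#' @param long data.frame with columns `time_s`, `site`, `sto2`.
#' @return data.frame with columns `time_s`, the four site columns (NA where
#'   absent) and `average`.
#' @export
buildSiteTable <- function(long) {
  stopifnot(all(c("time_s", "site", "sto2") %in% names(long)))
  times <- sort(unique(long$time_s))
  wide <- data.frame(time_s = times)
  for (s in MEASUREMENT_SITES) {
    m <- long[long$site == s, ]
    wide[[s]] <- m$sto2[match(times, m$time_s)]
  }
  wide$average <- vapply(seq_along(times), function(i) {
    v <- unlist(wide[i, MEASUREMENT_SITES])
    aggregateSites(v[!is.na(v)])
  }, numeric(1))
  wide
}

#' Phase-average StO2 before and after an intervention
#'
#' Pools every individual site value (not the per-row averages) strictly
#' before `splitTimeS` and at/after it, and reports each phase mean as a
#' percentage rounded half-away-from-zero to the nearest integer -- the
#' convention used for narrative summary percentages.
#'
#' @param long data.frame with columns `time_s`, `site`, `sto2`.
#' @param splitTimeS intervention time, s.
#' @return Named numeric `c(before = , after = )`, percentages.
#' @section Errors: `spx_phase_error` when either phase holds no rows.
#' @export
phaseAverage <- function(long, splitTimeS) {
  stopifnot(all(c("time_s", "sto2") %in% names(long)))
  pre <- long$sto2[long$time_s < splitTimeS]
  post <- long$sto2[long$time_s >= splitTimeS]
  if (!length(pre) || !length(post))
    spxStop("spx_phase_error",
            "split at %g s leaves an empty phase (%d before, %d after)",
            splitTimeS, length(pre), length(post))
  c(before = roundHalfAway(100 * mean(pre)),
    after = roundHalfAway(100 * mean(post)))
}

## Running median of `values` with symmetric shrinking windows at the edges
## (window 1, 3, ..., `window` then back down), the classic endrule.
shrinkingMedian <- function(values, window) {
  n <- length(values)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    stats::median(values[(i - h):(i + h)])
  }, numeric(1))
}

#' Median-smooth an StO2 series
#'
#' Running median with an odd window over the `ok` samples only; samples
#' flagged `ambient-light`, `probe-slip` or `fit-failed` are excluded from
#' every window. At the series edges the window shrinks symmetrically
#' (1, 3, ... samples). Flagged samples receive the median of the up-to-
#' `window` nearest ok samples. Timestamps and flags are unchanged.
#'
#' @param series an [StO2Series-class].
#' @param window odd window length in samples, `1 <= window <= length`.
#' @return A smoothed [StO2Series-class].
#' @section Errors: `spx_parameter_error` for an even window or one longer
#'   than the series.
#' @export
medianSmooth <- function(series, window = 5) {
  stopifnot(is(series, "StO2Series"))
  n <- length(series@times)
  if (window %% 2 != 1 || window < 1 || window > n)
    spxStop("spx_parameter_error",
            "window must be odd and between 1 and the series length (%d)", n)
  ok <- which(series@flags == "ok")
  out <- series@sto2
  if (length(ok) == 0L) return(series)
  sm <- shrinkingMedian(series@sto2[ok], min(window, length(ok) -
                                               (length(ok) + 1) %% 2))
  out[ok] <- sm
  bad <- setdiff(seq_len(n), ok)
  for (i in bad) {
    d <- abs(ok - i)
    nearest <- ok[order(d)][seq_len(min(window, length(ok)))]
    out[i] <- stats::median(series@sto2[nearest])
  }
  StO2Series(series@times, out, series@flags)
}

#' Analyse a pump step-down StO2 profile
#'
#' Given StO2 estimates at strictly decreasing pump flow levels, reports the
#' adjacent pair of levels with the largest StO2 decrease (ties broken
#' toward the higher-flow pair: the earliest physiological onset is the
#' conservative report) and the plateau onset -- the first level after
#' which every successive StO2 change stays within `plateauTol` through the
#' end of the run.
#'
#' @param flows pump flow levels, percent of full flow, strictly decreasing,
#'   length >= 3; or a data.frame with columns `flow_pct` and `sto2`.
#' @param sto2 StO2 estimate per level (fractions), or a list of
#'   [HbFit-class] objects of the same length as `flows`.
#' @param plateauTol plateau tolerance on successive absolute StO2 change
#'   (default 0.02).
#' @return A [PumpStepdownResult-class].
#' @section Errors: `spx_profile_error` with fewer than 3 levels;
#'   `spx_validation_error` for non-decreasing or duplicated flows.
#' @examples
#' stepdownProfile(c(100, 75, 50, 25, 0),
#'                 c(0.859, 0.819, 0.786, 0.593, 0.595))
#' @export
stepdownProfile <- function(flows, sto2 = NULL, plateauTol = 0.02) {
  if (is.data.frame(flows)) {
    stopifnot(all(c("flow_pct", "sto2") %in% names(flows)))
    sto2 <- flows$sto2
    flows <- flows$flow_pct
  }
  if (is.list(sto2))
    sto2 <- vapply(sto2, function(f) f@sto2, numeric(1))
  if (length(flows) < 3L)
    spxStop("spx_profile_error", "need at least 3 flow levels, got %d",
            length(flows))
  if (length(sto2) != length(flows))
    spxStop("spx_validation_error", "flows and sto2 differ in length")
  if (any(diff(flows) >= 0))
    spxStop("spx_validation_error",
            "flow levels must be strictly decreasing (duplicates included)")
  drops <- sto2[-length(sto2)] - sto2[-1]
  # first (highest-flow) pair among numerical ties wins
  iMax <- which(drops >= max(drops) - 1e-12)[1]
  deltas <- abs(diff(sto2))
  onset <- NA_real_
  for (i in seq_along(deltas)) {
    if (all(deltas[i:length(deltas)] <= plateauTol)) {
      onset <- flows[i]
      break
    }
  }
  new("PumpStepdownResult", flows = as.numeric(flows),
      sto2 = as.numeric(sto2),
      largestDropInterval = c(flows[iMax], flows[iMax + 1L]),
      plateauOnset = onset, plateauTol = plateauTol)
}

#' Event-detection thresholds
#'
#' Defaults are chosen to fire on an abrupt decompensation (StO2 falling by
#' a few percentage points in minutes with a synchronized collapse of the
#' flow index) and not on baseline jitter at ~1% intensity noise.
#'
#' @param sto2DropAbs minimum absolute drop of the median-smoothed StO2
#'   (default 0.02).
#' @param sto2SpanS span within which the StO2 drop must occur, s
#'   (default 600).
#' @param rbfiDropFrac minimum fractional RBFi drop (default 0.30).
#' @param rbfiSpanS span within which the RBFi drop must occur, s
#'   (default 600).
#' @param smoothWindow median window applied to the StO2 series before
#'   detection (default 5).
#' @return A named list of class `"eventConfig"`.
#' @export
eventConfig <- function(sto2DropAbs = 0.02, sto2SpanS = 600,
                        rbfiDropFrac = 0.30, rbfiSpanS = 600,
                        smoothWindow = 5) {
  structure(list(sto2DropAbs = sto2DropAbs, sto2SpanS = sto2SpanS,
                 rbfiDropFrac = rbfiDropFrac, rbfiSpanS = rbfiSpanS,
                 smoothWindow = smoothWindow),
            class = "eventConfig")
}

## Union of [t_i, t_j] intervals over sample pairs within `span` whose
## drop exceeds the threshold; dropFun(v_i, v_j) returns the drop measure.
dropIntervals <- function(times, values, span, threshold, dropFun) {
  idx <- which(!is.na(values))
  lo <- numeric(0); hi <- numeric(0)
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    for (jj in seq_along(idx)[-seq_len(ii)]) {
      j <- idx[jj]
      if (times[j] - times[i] > span) break
      if (dropFun(values[i], values[j]) > threshold) {
        lo <- c(lo, times[i]); hi <- c(hi, times[j])
      }
    }
  }
  if (!length(lo)) return(NULL)
  cbind(lo, hi)
}

#' Detect an abrupt synchronized perfusion drop
#'
#' Flags a decompensation-like event when the median-smoothed StO2 falls by
#' more than `sto2DropAbs` within `sto2SpanS` AND the flow index falls by
#' more than `rbfiDropFrac` (fractionally) within an overlapping span.
#' Synchronization is required: an StO2 drop without a flow-index drop (or
#' vice versa) returns `kind = "none"`.
#'
#' @param sto2Series an [StO2Series-class].
#' @param rbfiSeries an [RBFiSeries-class] overlapping it in time.
#' @param config an [eventConfig()].
#' @return An [EventWindow-class]; when an event is found, the window is the
#'   span of the overlapping qualifying drops.
#' @section Errors: `spx_alignment_error` when the series do not overlap.
#' @export
detectAbruptDrop <- function(sto2Series, rbfiSeries, config = eventConfig()) {
  stopifnot(is(sto2Series, "StO2Series"), is(rbfiSeries, "RBFiSeries"))
  lo <- max(min(sto2Series@times), min(rbfiSeries@times))
  hi <- min(max(sto2Series@times), max(rbfiSeries@times))
  if (lo >= hi)
    spxStop("spx_alignment_error", "StO2 and RBFi series do not overlap")
  sm <- medianSmooth(sto2Series,
                     min(config$smoothWindow,
                         length(sto2Series@times) -
                           (length(sto2Series@times) + 1) %% 2))
  sVals <- ifelse(sm@flags == "ok", sm@sto2, NA)
  sInt <- dropIntervals(sm@times, sVals, config$sto2SpanS,
                        config$sto2DropAbs, function(a, b) a - b)
  rInt <- dropIntervals(rbfiSeries@times, rbfiSeries@rbfi, config$rbfiSpanS,
                        config$rbfiDropFrac,
                        function(a, b) if (a > 0) (a - b) / a else 0)
  none <- new("EventWindow", start = NA_real_, end = NA_real_, kind = "none")
  if (is.null(sInt) || is.null(rInt)) return(none)
  # require temporal overlap between an StO2 drop and an RBFi drop
  best <- NULL
  for (i in seq_len(nrow(sInt))) {
    ov <- rInt[, "lo"] <= sInt[i, "hi"] & rInt[, "hi"] >= sInt[i, "lo"]
    if (any(ov)) {
      w <- c(min(sInt[i, "lo"], min(rInt[ov, "lo"])),
             max(sInt[i, "hi"], max(rInt[ov, "hi"])))
      if (is.null(best)) best <- w
      else best <- c(min(best[1], w[1]), max(best[2], w[2]))
    }
  }
  if (is.null(best)) return(none)
  new("EventWindow", start = best[1], end = best[2], kind = "decompensation",
      trigger = c(sto2_drop = config$sto2DropAbs,
                  rbfi_frac_drop = config$rbfiDropFrac))
}
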