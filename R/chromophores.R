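#' Load a haemoglobin extinction-coefficient table
#'
#' Reads oxy-/deoxy-haemoglobin molar extinction spectra, either the bundled
#' default table or a user-supplied file in the extinction-table CSV dialect
#' (header `wavelength_nm,eps_hbo2,eps_hb`, one row per wavelength, `.`
#' decimal separator).
#'
#' The bundled default (`inst/extdata/hb_extinction_synthetic.csv`) is a
#' synthetic reconstruction: a sum-of-Gaussian-bands model reproducing the
#' qualitative features of published haemoglobin compilations over
#' 450--650 nm (HbO2 beta/alpha double peak near 542/577 nm, a single broad
#' Hb band near 556 nm, isosbestic crossings near 529/544/573/591 nm). It is
#' intended for development, simulation and testing; substitute a measured
#' compilation for quantitative work on instrument data.
#'
#' @param source `"default"` for the bundled synthetic table, or a path to a
#'   CSV file in the dialect above.
#' @return A validated [ExtinctionTable-class] covering at least 500--600 nm
#'   at <= 2 nm spacing.
#' @section Errors: `spx_file_error` (missing file), `spx_parse_error`
#'   (malformed rows), `spx_order_error` (non-increasing wavelengths),
#'   `spx_coverage_error` (gap or insufficient span within 500--600 nm).
#' @examples
#' tab <- loadExtinctionTable()
#' range(wavelengths(tab))
#' @export
loadExtinctionTable <- function(source = "default") {
  path <- if (identical(source, "default")) {
    system.file("extdata", "hb_extinction_synthetic.csv",
                package = "spectroxy", mustWork = FALSE)
  } else source
  if (!nzchar(path) || !file.exists(path))
    spxStop("spx_file_error", "extinction table file not found: '%s'", source)

  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e)
      spxStop("spx_parse_error", "cannot parse extinction table '%s': %s",
              path, conditionMessage(e)))
  need <- c("wavelength_nm", "eps_hbo2", "eps_hb")
  if (!all(need %in% names(df)))
    spxStop("spx_parse_error",
            "extinction table must have columns %s", paste(need, collapse = ","))
  for (cl in need) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  if (anyNA(df$wavelength_nm) || anyNA(df$eps_hbo2) || anyNA(df$eps_hb))
    spxStop("spx_parse_error", "extinction table contains non-numeric rows")
  if (any(diff(df$wavelength_nm) <= 0))
    spxStop("spx_order_error",
            "extinction table wavelengths must be strictly increasing")
  w <- df$wavelength_nm
  if (min(w) > HB_WINDOW_NM[1] || max(w) < HB_WINDOW_NM[2])
    spxStop("spx_coverage_error",
            "extinction table must cover [%g, %g] nm (got [%g, %g])",
            HB_WINDOW_NM[1], HB_WINDOW_NM[2], min(w), max(w))
  inWin <- w >= HB_WINDOW_NM[1] & w <= HB_WINDOW_NM[2]
  if (max(diff(w[inWin])) > 2)
    spxStop("spx_coverage_error",
            "extinction table spacing exceeds 2 nm within [%g, %g] nm",
            HB_WINDOW_NM[1], HB_WINDOW_NM[2])
  new("ExtinctionTable", wavelength = w, epsHbO2 = df$eps_hbo2,
      epsHb = df$eps_hb,
      source = if (identical(source, "default"))
        "bundled synthetic Gaussian-band table" else as.character(source))
}

#' Resample an extinction table onto a new wavelength grid
#'
#' Linear interpolation of both coefficient columns onto `target`. Linear
#' (not spline) interpolation keeps every interpolated value bounded by its
#' bracketing tabulated values, which matters near the sharp beta/alpha
#' haemoglobin bands. The input table is not modified.
#'
#' @param table an [ExtinctionTable-class].
#' @param target numeric vector of target wavelengths, nm, strictly
#'   increasing, within the table's span (no extrapolation).
#' @return A new [ExtinctionTable-class] on `target`.
#' @section Errors: `spx_range_error` if `target` extends beyond the table.
#' @examples
#' tab <- loadExtinctionTable()
#' fine <- resampleExtinction(tab, seq(500, 600, by = 0.5))
#' @export
resampleExtinction <- function(table, target) {
  stopifnot(is(table, "ExtinctionTable"))
  target <- as.numeric(target)
  wv <- validWavelengths(target)
  if (is.character(wv)) spxStop("spx_parameter_error", "target grid: %s", wv)
  if (min(target) < min(table@wavelength) ||
      max(target) > max(table@wavelength))
    spxStop("spx_range_error",
            "target grid [%g, %g] nm extends beyond table span [%g, %g] nm",
            min(target), max(target), min(table@wavelength),
            max(table@wavelength))
  new("ExtinctionTable", wavelength = target,
      epsHbO2 = stats::approx(table@wavelength, table@epsHbO2,
                              xout = target)$y,
      epsHb = stats::approx(table@wavelength, table@epsHb, xout = target)$y,
      source = table@source)
}
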