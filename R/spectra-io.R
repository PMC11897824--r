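## Spectrum CSV dialect:
##   optional '# key: value' comment header lines
##   (keys: kind, timestamp_s, integration_s, site, notes), then
##   'wavelength_nm,value' with one row per wavelength, ascending.
## All files UTF-8, LF endings, '.' decimal separator.

META_KEYS_NUMERIC <- c("timestamp_s", "integration_s")
META_KEYS <- c("kind", META_KEYS_NUMERIC, "site", "notes")

#' Read a spectrum from the spectrum CSV dialect
#'
#' Parses a two-column `wavelength_nm,value` file with an optional
#' `# key: value` comment header carrying acquisition metadata. A `kind`
#' header key, if present, must agree with the `kind` argument.
#'
#' @param path file to read.
#' @param kind expected spectrum kind (`"reflectance"`, `"reference"` or
#'   `"absorbance"`).
#' @return A validated [Spectrum-class].
#' @section Errors: `spx_file_error`, `spx_parse_error`, `spx_order_error`,
#'   `spx_validation_error` (e.g. negative counts for reflectance).
#' @seealso [writeSpectrum()]
#' @export
readSpectrum <- function(path, kind = "reflectance") {
  if (!file.exists(path))
    spxStop("spx_file_error", "spectrum file not found: '%s'", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  isMeta <- startsWith(trimws(lines), "#")
  meta <- parseMetaHeader(lines[isMeta], path)
  if (!is.null(meta$kind)) {
    if (!identical(meta$kind, kind))
      spxStop("spx_parse_error",
              "'%s' declares kind '%s' but '%s' was requested",
              path, meta$kind, kind)
    meta$kind <- NULL
  }
  body <- lines[!isMeta & nzchar(trimws(lines))]
  if (length(body) < 1L)
    spxStop("spx_parse_error", "'%s' has no data rows", path)
  if (!identical(trimws(body[1]), "wavelength_nm,value"))
    spxStop("spx_parse_error",
            "'%s' must start its data with header 'wavelength_nm,value'",
            path)
  body <- body[-1]
  if (length(body) == 0L)
    spxStop("spx_parse_error", "'%s' has a header but no data rows", path)
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    spxStop("spx_parse_error", "'%s' has rows without exactly 2 fields", path)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 2, byrow = TRUE)
  if (anyNA(m))
    spxStop("spx_parse_error", "'%s' has non-numeric fields", path)
  if (any(diff(m[, 1]) <= 0))
    spxStop("spx_order_error",
            "'%s': wavelengths must be strictly increasing", path)
  if (kind %in% c("reflectance", "reference") && any(m[, 2] < 0))
    spxStop("spx_validation_error",
            "'%s': %s values must be >= 0", path, kind)
  Spectrum(m[, 1], m[, 2], kind = kind, meta = meta)
}

parseMetaHeader <- function(metaLines, path) {
  meta <- list()
  for (ln in metaLines) {
    txt <- sub("^\\s*#\\s*", "", ln)
    if (!grepl(":", txt, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", txt))
    val <- trimws(sub("^[^:]*:", "", txt))
    if (!key %in% META_KEYS) next
    if (key %in% META_KEYS_NUMERIC) {
      val <- suppressWarnings(as.numeric(val))
      if (is.na(val))
        spxStop("spx_parse_error", "'%s': header key '%s' is not numeric",
                path, key)
    }
    meta[[key]] <- val
  }
  meta
}

#' Write a spectrum in the spectrum CSV dialect
#'
#' Metadata keys are written as `# key: value` comment lines so that
#' [readSpectrum()] inverts the writer exactly; values round-trip to at
#' least 6 significant figures. The first data row holds the smallest
#' wavelength.
#'
#' @param spectrum a valid [Spectrum-class] with at least one point.
#' @param path output file.
#' @return `path`, invisibly.
#' @section Errors: `spx_validation_error` for a zero-length spectrum,
#'   `spx_io_error` for an unwritable path.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  if (length(spectrum@wavelength) == 0L)
    spxStop("spx_validation_error", "refusing to write a zero-length spectrum")
  validObject(spectrum)
  meta <- spectrum@meta
  hdr <- c(sprintf("# kind: %s", spectrum@kind),
           vapply(names(meta), function(k)
             sprintf("# %s: %s", k, format(meta[[k]], digits = 15)),
             character(1)))
  rows <- sprintf("%s,%s",
                  formatC(spectrum@wavelength, digits = 10, format = "g"),
                  formatC(spectrum@values, digits = 10, format = "g"))
  out <- tryCatch(
    writeLines(c(hdr, "wavelength_nm,value", rows), path, sep = "\n"),
    error = function(e)
      spxStop("spx_io_error", "cannot write '%s': %s", path,
              conditionMessage(e)))
  invisible(path)
}

#' Put two spectra on a common wavelength grid
#'
#' Restricts both spectra to their overlapping span (which must cover the
#' 500--600 nm haemoglobin window). Grids equal to within `toleranceNm`
#' pointwise are used as-is; otherwise the coarser spectrum's grid wins and
#' the other spectrum is linearly interpolated onto it. The returned spectra
#' always share an identical grid.
#'
#' @param a,b [Spectrum-class] objects.
#' @param toleranceNm pointwise tolerance for treating grids as equal
#'   (default 0.5 nm).
#' @param window wavelength window the overlap must cover (default
#'   `c(500, 600)`).
#' @return A list `list(a = , b = )` of spectra on the common grid.
#' @section Errors: `spx_alignment_error` when the overlap does not cover
#'   `window`.
#' @export
alignGrids <- function(a, b, toleranceNm = 0.5, window = HB_WINDOW_NM) {
  stopifnot(is(a, "Spectrum"), is(b, "Spectrum"))
  lo <- max(min(a@wavelength), min(b@wavelength))
  hi <- min(max(a@wavelength), max(b@wavelength))
  if (lo > window[1] || hi < window[2])
    spxStop("spx_alignment_error",
            "spectra overlap [%g, %g] nm does not cover [%g, %g] nm",
            lo, hi, window[1], window[2])
  cutTo <- function(s, grid, values) {
    keep <- grid >= lo & grid <= hi
    list(w = grid[keep], v = values[keep])
  }
  ca <- cutTo(a, a@wavelength, a@values)
  cb <- cutTo(b, b@wavelength, b@values)
  sameGrid <- length(ca$w) == length(cb$w) &&
    all(abs(ca$w - cb$w) <= toleranceNm)
  if (sameGrid && all(ca$w == cb$w)) {
    # identical grids: pass values through untouched
    outA <- ca$v; outB <- cb$v; grid <- ca$w
  } else {
    # coarser grid (larger mean spacing) wins; interpolate the other
    spacing <- function(w) if (length(w) > 1) mean(diff(w)) else Inf
    # the winning grid is trimmed to the other spectrum's span so no point
    # requires extrapolation
    span <- c(max(min(ca$w), min(cb$w)), min(max(ca$w), max(cb$w)))
    if (spacing(ca$w) >= spacing(cb$w)) {
      keep <- ca$w >= span[1] & ca$w <= span[2]
      grid <- ca$w[keep]
      outA <- ca$v[keep]
      outB <- stats::approx(cb$w, cb$v, xout = grid, rule = 1)$y
    } else {
      keep <- cb$w >= span[1] & cb$w <= span[2]
      grid <- cb$w[keep]
      outB <- cb$v[keep]
      outA <- stats::approx(ca$w, ca$v, xout = grid, rule = 1)$y
    }
    if (length(grid) == 0L || anyNA(outA) || anyNA(outB) ||
        min(grid) > window[1] || max(grid) < window[2])
      spxStop("spx_alignment_error",
              "common grid does not cover [%g, %g] nm after alignment",
              window[1], window[2])
  }
  list(a = Spectrum(grid, outA, kind = a@kind, meta = a@meta),
       b = Spectrum(grid, outB, kind = b@kind, meta = b@meta))
}

#' Read / write StO2 and RBFi series CSV files
#'
#' StO2 series files have header `time_s,sto2,flag`; RBFi files have
#' `time_s,rbfi`. Both are UTF-8 with `.` decimal separator.
#'
#' @param path file path.
#' @return [StO2Series-class] / [RBFiSeries-class]; writers return `path`
#'   invisibly.
#' @name series-io
NULL

#' @rdname series-io
#' @export
readStO2Series <- function(path) {
  if (!file.exists(path))
    spxStop("spx_file_error", "series file not found: '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "sto2", "flag") %in% names(df)))
    spxStop("spx_parse_error", "'%s' must have columns time_s,sto2,flag", path)
  if (any(diff(df$time_s) <= 0))
    spxStop("spx_order_error", "'%s': times must be strictly increasing", path)
  StO2Series(df$time_s, df$sto2, df$flag)
}

#' @rdname series-io
#' @param series the series object to write.
#' @export
writeStO2Series <- function(series, path) {
  stopifnot(is(series, "StO2Series"))
  df <- data.frame(time_s = series@times,
                   sto2 = format(series@sto2, digits = 10, trim = TRUE),
                   flag = series@flags)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname series-io
#' @export
readRBFiSeries <- function(path) {
  if (!file.exists(path))
    spxStop("spx_file_error", "series file not found: '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "rbfi") %in% names(df)))
    spxStop("spx_parse_error", "'%s' must have columns time_s,rbfi", path)
  if (any(diff(df$time_s) <= 0))
    spxStop("spx_order_error", "'%s': times must be strictly increasing", path)
  RBFiSeries(df$time_s, df$rbfi)
}

#' @rdname series-io
#' @export
writeRBFiSeries <- function(series, path) {
  stopifnot(is(series, "RBFiSeries"))
  df <- data.frame(time_s = series@times,
                   rbfi = format(series@rbfi, digits = 10, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-site StO2 table from the site-table CSV dialect
#'
#' The dialect is long-form `time_s,site,sto2`, one row per site
#' measurement; sites must come from the hand-held protocol's four labels
#' (hilum, superior, lateral, inferior).
#'
#' @param path file path.
#' @return A long-form data.frame with columns `time_s`, `site`, `sto2`.
#' @export
readSiteTable <- function(path) {
  if (!file.exists(path))
    spxStop("spx_file_error", "site table not found: '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "site", "sto2") %in% names(df)))
    spxStop("spx_parse_error", "'%s' must have columns time_s,site,sto2", path)
  if (!all(df$site %in% MEASUREMENT_SITES))
    spxStop("spx_validation_error", "'%s': unknown site label(s): %s", path,
            paste(setdiff(df$site, MEASUREMENT_SITES), collapse = ", "))
  if (any(df$sto2 < 0 | df$sto2 > 1))
    spxStop("spx_validation_error", "'%s': sto2 must lie in [0, 1]", path)
  df[c("time_s", "site", "sto2")]
}
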