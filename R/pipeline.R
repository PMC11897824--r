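#' Assemble a run configuration
#'
#' One serializable object drives a whole analysis run; archiving it (plus
#' the input files) is sufficient to reproduce every output bit-identically.
#'
#' @param referencePath path to the lamp/reference spectrum CSV.
#' @param spectraDir directory of sample spectrum CSVs (read in lexical
#'   order), or `NULL` when `manifest` is given.
#' @param manifest optional data.frame with column `path` (and `flow_pct`
#'   for step-down runs) overriding `spectraDir`.
#' @param extinctionSource `"default"` or a path, passed to
#'   [loadExtinctionTable()].
#' @param method absorption-inference method (see [inferAbsorption()]).
#' @param anchorScale logical, anchor-band amplitude matching.
#' @param fit a [fitConfig()].
#' @param quality a [qualityConfig()].
#' @param smoothWindow median window for series smoothing (odd).
#' @param event an [eventConfig()].
#' @param outputDir directory for outputs (`NULL` = no files written).
#' @param seed integer seed recorded in the run log.
#' @return A named list of class `"runConfig"`.
#' @export
runConfig <- function(referencePath, spectraDir = NULL, manifest = NULL,
                      extinctionSource = "default",
                      method = "absolute-difference", anchorScale = TRUE,
                      fit = fitConfig(), quality = qualityConfig(),
                      smoothWindow = 5, event = eventConfig(),
                      outputDir = NULL, seed = 1L) {
  structure(list(referencePath = referencePath, spectraDir = spectraDir,
                 manifest = manifest, extinctionSource = extinctionSource,
                 method = method, anchorScale = anchorScale, fit = fit,
                 quality = quality, smoothWindow = smoothWindow,
                 event = event, outputDir = outputDir,
                 seed = as.integer(seed)),
            class = "runConfig")
}

#' Load a run configuration from a YAML or JSON file
#'
#' Keys mirror the [runConfig()] arguments; nested `fit`, `quality` and
#' `event` blocks mirror [fitConfig()], [qualityConfig()] and
#' [eventConfig()] arguments.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `"runConfig"` list.
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path))
    spxStop("spx_config_error", "config file not found: '%s'", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw
  for (blk in c("fit", "quality", "event")) {
    if (!is.null(raw[[blk]])) {
      ctor <- switch(blk, fit = fitConfig, quality = qualityConfig,
                     event = eventConfig)
      args[[blk]] <- do.call(ctor, raw[[blk]])
    }
  }
  do.call(runConfig, args)
}

## FNV-1a over the serialized config: a stable short fingerprint for run logs.
configHash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(config[!vapply(config, is.null,
                                                     logical(1))],
                                      auto_unbox = TRUE, digits = NA,
                                      force = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

collectSpectrumPaths <- function(config) {
  if (!is.null(config$manifest)) {
    if (is.null(config$manifest$path))
      spxStop("spx_config_error", "manifest must have a 'path' column")
    return(as.character(config$manifest$path))
  }
  if (is.null(config$spectraDir))
    spxStop("spx_config_error", "either spectraDir or manifest is required")
  if (!dir.exists(config$spectraDir))
    spxStop("spx_config_error", "spectra directory not found: '%s'",
            config$spectraDir)
  paths <- sort(list.files(config$spectraDir, pattern = "\\.csv$",
                           full.names = TRUE))
  paths <- paths[!basename(paths) %in% c("reference.csv", "rbfi.csv")]
  if (length(paths) == 0L)
    spxStop("spx_config_error", "no spectrum files in '%s'",
            config$spectraDir)
  paths
}

#' Fit one spectrum file end to end
#'
#' Convenience wrapper: read, align, infer absorption, fit.
#'
#' @param path spectrum CSV path.
#' @param referencePath lamp spectrum CSV path.
#' @param config a `"runConfig"` (only the preprocessing/fit fields are
#'   used).
#' @return An [HbFit-class].
#' @export
fitSpectrumFile <- function(path, referencePath,
                            config = runConfig(referencePath)) {
  reference <- readSpectrum(referencePath, kind = "reference")
  extinction <- loadExtinctionTable(config$extinctionSource)
  s <- readSpectrum(path, kind = "reflectance")
  a <- inferAbsorption(s, reference, method = config$method,
                       window = config$fit$windowNm,
                       anchorScale = config$anchorScale,
                       anchorBandNm = config$quality$anchorBandNm)
  fitAbsorption(a, extinction, config$fit)
}

#' Run the continuous-fit pipeline over a set of spectra
#'
#' Each spectrum is quality-flagged (ambient light against the reference;
#' probe slip against the preceding spectrum), converted to an inferred
#' absorption spectrum and fitted; the StO2 estimates are assembled into a
#' flagged time series. Individual bad spectra are flagged, never abort the
#' run. When `config$outputDir` is set, `sto2.csv`, `fits.json` and
#' `runlog.json` (config hash, package version, per-flag counts) are
#' written there.
#'
#' @param config a [runConfig()] with a reference and spectra source.
#' @return Invisibly, `list(series, fits, flags)` where `series` is an
#'   [StO2Series-class] and `fits` a list of [HbFit-class].
#' @section Errors: `spx_config_error` for a missing reference or empty
#'   spectra source.
#' @export
runFit <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  if (is.null(config$referencePath) || !file.exists(config$referencePath))
    spxStop("spx_config_error", "reference spectrum not found: '%s'",
            config$referencePath %||% "<missing>")
  reference <- readSpectrum(config$referencePath, kind = "reference")
  extinction <- loadExtinctionTable(config$extinctionSource)
  paths <- collectSpectrumPaths(config)

  n <- length(paths)
  times <- numeric(n); sto2v <- rep(NA_real_, n); flags <- character(n)
  fits <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    s <- readSpectrum(paths[i], kind = "reflectance")
    times[i] <- specMeta(s)$timestamp_s %||% (i - 1)
    flag <- flagQuality(s, reference, previous = prev,
                        config = config$quality)
    # the current spectrum becomes the slip baseline unless light-corrupted,
    # so a coupling change flags only the transition sample
    if (flag != "ambient-light") prev <- s
    fit <- tryCatch({
      a <- inferAbsorption(s, reference, method = config$method,
                           window = config$fit$windowNm,
                           anchorScale = config$anchorScale,
                           anchorBandNm = config$quality$anchorBandNm)
      fitAbsorption(a, extinction, config$fit)
    }, spx_error = function(e) NULL)
    fits[[i]] <- fit
    if (is.null(fit) || is.na(fit@sto2) || !fit@converged) {
      if (flag == "ok") flag <- "fit-failed"
    } else sto2v[i] <- fit@sto2
    flags[i] <- flag
  }
  ord <- order(times)
  series <- StO2Series(times[ord], sto2v[ord], flags[ord])
  out <- list(series = series, fits = fits[ord],
              flags = table(factor(flags, levels = QUALITY_FLAGS)))

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    writeStO2Series(series, file.path(config$outputDir, "sto2.csv"))
    jsonlite::write_json(lapply(out$fits, fitReport),
                         file.path(config$outputDir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(config_hash = configHash(config),
           package_version = as.character(utils::packageVersion("spectroxy")),
           n_spectra = n, seed = config$seed,
           flag_counts = as.list(out$flags)),
      file.path(config$outputDir, "runlog.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

## Per-spectrum fit report (JSON-ready)
fitReport <- function(fit) {
  if (is.null(fit)) return(list(converged = FALSE))
  list(a_hbo2 = fit@aHbO2, a_hb = fit@aHb,
       background = as.numeric(fit@background), sto2 = fit@sto2,
       rss = fit@rss, converged = fit@converged, n_points = fit@nPoints,
       window_nm = fit@window, lambda_c = fit@lambdaC)
}

#' Run the pump step-down analysis
#'
#' Fits one spectrum per pump-flow level and summarises the StO2-vs-flow
#' profile via [stepdownProfile()]. When `config$outputDir` is set,
#' `stepdown.csv` (`flow_pct,sto2`) and `stepdown.json` are written.
#'
#' @param config a [runConfig()].
#' @param manifest data.frame with columns `flow_pct` (strictly decreasing,
#'   >= 3 unique levels) and `path`.
#' @param plateauTol plateau tolerance (default 0.02).
#' @return A [PumpStepdownResult-class].
#' @export
runStepdown <- function(config, manifest, plateauTol = 0.02) {
  stopifnot(inherits(config, "runConfig"))
  if (!all(c("flow_pct", "path") %in% names(manifest)))
    spxStop("spx_config_error", "manifest needs columns flow_pct, path")
  if (anyDuplicated(manifest$flow_pct))
    spxStop("spx_validation_error", "duplicate flow level in manifest")
  if (nrow(manifest) < 3L)
    spxStop("spx_profile_error", "need at least 3 flow levels, got %d",
            nrow(manifest))
  fits <- lapply(manifest$path, fitSpectrumFile,
                 referencePath = config$referencePath, config = config)
  res <- stepdownProfile(manifest$flow_pct, fits, plateauTol = plateauTol)
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(flow_pct = res@flows, sto2 = res@sto2),
                     file.path(config$outputDir, "stepdown.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(flow_pct = res@flows, sto2 = res@sto2,
           largest_drop_interval = res@largestDropInterval,
           plateau_onset = res@plateauOnset, plateau_tol = res@plateauTol),
      file.path(config$outputDir, "stepdown.json"),
      auto_unbox = TRUE, digits = NA)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
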