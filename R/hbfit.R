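#' Fitting configuration for the haemoglobin absorption model
#'
#' @param backgroundOrder polynomial degree of the background term
#'   (default 2: absorbs lamp-shape and scattering trends without competing
#'   with the ~30 nm-wide haemoglobin bands).
#' @param windowNm fit window, nm (default 500--600).
#' @param maxIterations optimizer iteration cap (default 200).
#' @param convergenceTol relative residual-change tolerance (default 1e-10).
#' @return A named list of class `"fitConfig"`.
#' @export
fitConfig <- function(backgroundOrder = 2, windowNm = HB_WINDOW_NM,
                      maxIterations = 200, convergenceTol = 1e-10) {
  if (backgroundOrder < 0)
    spxStop("spx_parameter_error", "backgroundOrder must be >= 0")
  structure(list(backgroundOrder = as.integer(backgroundOrder),
                 windowNm = windowNm,
                 maxIterations = as.integer(maxIterations),
                 convergenceTol = convergenceTol),
            class = "fitConfig")
}

## Background basis: powers of the centred, scaled coordinate
## ((lambda - lambdaC) / 50); centring conditions the normal equations.
backgroundBasis <- function(grid, order, lambdaC) {
  x <- (grid - lambdaC) / 50
  outer(x, 0:order, `^`)
}

#' Evaluate the haemoglobin absorption model
#'
#' Computes `aHb * epsHb(lambda) + aHbO2 * epsHbO2(lambda) +
#' sum_k b_k ((lambda - lambdaC)/50)^k` on `grid`. The amplitudes are the
#' combined (uncalibrated) products of path length, concentration and
#' ln(10); only their ratio is identifiable from a fit.
#'
#' @param aHbO2,aHb non-negative amplitudes.
#' @param background numeric vector `b0..bk` of background coefficients.
#' @param extinction an [ExtinctionTable-class].
#' @param grid wavelengths, nm, within the extinction table's span.
#' @param lambdaC centre of the background coordinate (default: midpoint of
#'   `grid`'s range).
#' @return An absorbance [Spectrum-class] on `grid`.
#' @section Errors: `spx_range_error` when `grid` leaves the extinction
#'   coverage; `spx_parameter_error` for negative amplitudes.
#' @export
evaluateModel <- function(aHbO2, aHb, background, extinction, grid,
                          lambdaC = mean(range(grid))) {
  if (aHbO2 < 0 || aHb < 0)
    spxStop("spx_parameter_error", "amplitudes must be >= 0")
  eps <- resampleExtinction(extinction, grid)
  vals <- aHbO2 * eps@epsHbO2 + aHb * eps@epsHb
  if (length(background))
    vals <- vals +
      drop(backgroundBasis(grid, length(background) - 1L, lambdaC) %*%
             background)
  Spectrum(grid, vals, kind = "absorbance")
}

#' Tissue oxygen saturation from fitted amplitudes
#'
#' `StO2 = aHbO2 / (aHb + aHbO2)`; because path length and ln(10) enter
#' both amplitudes identically, this equals the concentration ratio
#' `cHbO2 / (cHb + cHbO2)` exactly.
#'
#' @param aHbO2,aHb non-negative amplitudes.
#' @return Saturation fraction in \[0, 1\].
#' @section Errors: `spx_undefined_saturation_error` when both amplitudes
#'   are zero (callers convert this to a `fit-failed` flag).
#' @examples
#' computeStO2(0.7, 0.3)
#' @export
computeStO2 <- function(aHbO2, aHb) {
  if (aHbO2 < 0 || aHb < 0)
    spxStop("spx_parameter_error", "amplitudes must be >= 0")
  if (aHbO2 + aHb <= 0)
    spxStop("spx_undefined_saturation_error",
            "StO2 undefined: both amplitudes are zero")
  aHbO2 / (aHb + aHbO2)
}

## Exact bound-constrained linear least squares for this model: only the two
## amplitude coordinates are bounded (>= 0), so the optimum's active set is
## one of four; solve each reduced linear system and keep the feasible
## solution with the smallest RSS.
solveConstrainedLinear <- function(X, y) {
  n <- ncol(X)
  candidates <- list(c(), 1L, 2L, c(1L, 2L))  # indices clamped to zero
  best <- NULL
  for (zero in candidates) {
    free <- setdiff(seq_len(n), zero)
    beta <- rep(0, n)
    if (length(free)) {
      fit <- tryCatch(qr.solve(qr(X[, free, drop = FALSE]), y),
                      error = function(e) NULL)
      if (is.null(fit)) next
      beta[free] <- fit
    }
    if (any(beta[1:2] < -1e-12)) next
    beta[1:2] <- pmax(beta[1:2], 0)
    rss <- sum((y - drop(X %*% beta))^2)
    if (is.null(best) || rss < best$rss) best <- list(beta = beta, rss = rss)
  }
  best
}

#' Fit the haemoglobin absorption model to an inferred absorption spectrum
#'
#' Least-squares fit of [evaluateModel()] to `absorbance` over the fit
#' window, with the two haemoglobin amplitudes bounded at zero (so the
#' derived StO2 stays in \[0, 1\]) and the polynomial background free. The
#' model is linear in all parameters; the exact non-negative solution of the
#' linear system initializes a bound-constrained Levenberg-Marquardt
#' refinement ([minpack.lm::nls.lm]), making the result deterministic.
#'
#' When the optimizer hits its iteration cap the best-so-far parameters are
#' returned with `converged = FALSE` (never an exception). When both
#' amplitudes vanish, StO2 is recorded as `NA` -- never clamped -- and
#' callers should propagate a `fit-failed` flag.
#'
#' @param absorbance an absorbance [Spectrum-class] covering the fit window.
#' @param extinction an [ExtinctionTable-class] covering the window.
#' @param config a [fitConfig()].
#' @return An [HbFit-class].
#' @section Errors: `spx_coverage_error` when the spectrum does not cover
#'   the window or has fewer than `backgroundOrder + 3` points in it.
#' @examples
#' tab <- loadExtinctionTable()
#' truth <- evaluateModel(0.7e-5, 0.3e-5, c(0.01, 0, 0), tab, 500:600)
#' fitAbsorption(truth, tab)
#' @export
fitAbsorption <- function(absorbance, extinction, config = fitConfig()) {
  stopifnot(is(absorbance, "Spectrum"), is(extinction, "ExtinctionTable"))
  win <- config$windowNm
  keep <- absorbance@wavelength >= win[1] & absorbance@wavelength <= win[2]
  grid <- absorbance@wavelength[keep]
  y <- absorbance@values[keep]
  if (length(grid) == 0 || min(grid) > win[1] + 2 || max(grid) < win[2] - 2)
    spxStop("spx_coverage_error",
            "absorbance spectrum does not cover the fit window [%g, %g] nm",
            win[1], win[2])
  k <- config$backgroundOrder
  if (length(grid) < k + 3L)
    spxStop("spx_coverage_error",
            "need at least %d points in the window, got %d", k + 3L,
            length(grid))
  lambdaC <- mean(win)
  eps <- resampleExtinction(extinction, grid)
  X <- cbind(eps@epsHbO2, eps@epsHb, backgroundBasis(grid, k, lambdaC))

  newFit <- function(beta, rss, converged) {
    a <- pmax(beta[1:2], 0)
    s <- if (sum(a) > 0) a[1] / sum(a) else NA_real_
    new("HbFit", aHbO2 = a[1], aHb = a[2],
        background = beta[-(1:2)], sto2 = s, rss = max(rss, 0),
        converged = converged, nPoints = length(grid), window = win,
        lambdaC = lambdaC)
  }

  init <- solveConstrainedLinear(X, y)
  if (is.null(init))  # degenerate design (e.g. collinear extinction columns)
    return(newFit(rep(0, ncol(X)), sum(y^2), FALSE))

  res <- tryCatch(
    minpack.lm::nls.lm(
      par = init$beta,
      fn = function(p) y - drop(X %*% p),
      lower = c(0, 0, rep(-Inf, k + 1L)),
      control = minpack.lm::nls.lm.control(
        maxiter = config$maxIterations, ftol = config$convergenceTol)),
    error = function(e) NULL)
  if (is.null(res))
    return(newFit(init$beta, init$rss, FALSE))
  rss <- sum(res$fvec^2)
  # keep whichever of the exact linear solution / LM refinement is better
  if (init$rss < rss) {
    beta <- init$beta; rss <- init$rss
  } else beta <- res$par
  converged <- res$info %in% 1:4 && res$niter < config$maxIterations
  newFit(beta, rss, converged)
}
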