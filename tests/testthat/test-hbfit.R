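grid <- 500:600
eps <- resampleExtinction(hbTab, grid)

test_that("evaluateModel matches a hand-computed weighted sum at spot wavelengths", {
  set.seed(42)
  a1 <- runif(1, 0, 1e-5); a2 <- runif(1, 0, 1e-5); bg <- rnorm(3, 0, 0.01)
  m <- evaluateModel(a1, a2, bg, hbTab, grid, lambdaC = 550)
  for (wl in c(510, 550, 590)) {
    i <- which(grid == wl)
    x <- (wl - 550) / 50
    expect_equal(specValues(m)[i],
                 a1 * epsHbO2(eps)[i] + a2 * epsHb(eps)[i] +
                   bg[1] + bg[2] * x + bg[3] * x^2,
                 tolerance = 1e-12)
  }
  # zero case and single-species proportionality
  expect_equal(specValues(evaluateModel(0, 0, c(0, 0, 0), hbTab, grid)),
               rep(0, length(grid)))
  pure <- evaluateModel(1e-5, 0, numeric(0), hbTab, grid)
  expect_equal(specValues(pure) / epsHbO2(eps), rep(1e-5, length(grid)))
  expect_error(evaluateModel(-1, 0, 0, hbTab, grid),
               class = "spx_parameter_error")
})

test_that("noiseless synthetic absorbance is recovered with the true StO2", {
  aTot <- 5e-6
  cases <- list(c(0.7, 0.3), c(1, 0), c(0.5, 0.5), c(0, 1))
  for (cs in cases) {
    truth <- evaluateModel(cs[1] * aTot, cs[2] * aTot, c(0.02, -0.01, 0.003),
                           hbTab, grid, lambdaC = 550)
    f <- fitAbsorption(truth, hbTab)
    expected <- cs[1] / sum(cs)
    tol <- if (cs[1] %in% c(0, 1) || cs[1] == cs[2]) 1e-6 else 1e-3
    expect_equal(sto2(f), expected, tolerance = tol)
    expect_true(f@converged)
    expect_lt(f@rss, 1e-12)
  }
})

test_that("StO2 computation handles boundaries and the degenerate case", {
  expect_equal(computeStO2(0.5, 0), 1)
  expect_equal(computeStO2(0, 0.5), 0)
  for (x in c(1e-8, 1, 1e4)) expect_equal(computeStO2(x, x), 0.5)
  expect_error(computeStO2(0, 0),
               class = "spx_undefined_saturation_error")
  expect_error(computeStO2(-1, 1), class = "spx_parameter_error")
})

test_that("fits are scale-equivariant and StO2 is scale-invariant", {
  truth <- evaluateModel(3e-6, 2e-6, c(0.05, -0.01, 0.002), hbTab, grid,
                         lambdaC = 550)
  f1 <- fitAbsorption(truth, hbTab)
  for (k in c(0.01, 7, 1e3)) {
    fk <- fitAbsorption(Spectrum(grid, specValues(truth) * k, "absorbance"),
                        hbTab)
    expect_equal(fittedAmplitudes(fk), fittedAmplitudes(f1) * k,
                 tolerance = 1e-6)
    expect_equal(backgroundCoefs(fk), backgroundCoefs(f1) * k,
                 tolerance = 1e-6)
    expect_equal(sto2(fk), sto2(f1), tolerance = 1e-6)
  }
})

test_that("order-0 fits agree with an exhaustive amplitude grid search", {
  # independent oracle: 201x201 grid over the amplitudes, offset profiled
  # out in closed form for each grid point
  set.seed(99)
  e1 <- epsHbO2(eps); e2 <- epsHb(eps)
  for (rep in 1:5) {
    aT <- c(3e-6, 6e-6)[1 + rep %% 2]
    s <- runif(1)
    y <- s * aT * e1 + (1 - s) * aT * e2 + runif(1, -0.01, 0.01)
    f <- fitAbsorption(Spectrum(grid, y, "absorbance"), hbTab,
                       fitConfig(backgroundOrder = 0))
    cell <- 2 * aT / 200
    ax <- seq(0, 2 * aT, length.out = 201)
    # centred RSS for y - a1 e1 - a2 e2 expands into scalar products, so the
    # full 201x201 grid is enumerable without inner loops
    n <- length(y)
    best <- c(NA, NA); bestR <- Inf
    for (a1 in ax) {
      r0 <- y - a1 * e1
      ss <- sum(r0^2) - 2 * ax * sum(r0 * e2) + ax^2 * sum(e2^2)
      mn <- mean(r0) - ax * mean(e2)
      rss <- ss - n * mn^2
      i <- which.min(rss)
      if (rss[i] < bestR) { bestR <- rss[i]; best <- c(a1, ax[i]) }
    }
    expect_lte(abs(fittedAmplitudes(f)[["aHbO2"]] - best[1]), cell + 1e-15)
    expect_lte(abs(fittedAmplitudes(f)[["aHb"]] - best[2]), cell + 1e-15)
  }
})

test_that("the fitted residual never exceeds the background-only residual", {
  set.seed(4)
  for (rep in 1:20) {
    y <- runif(1, 0, 2e-5) * epsHbO2(eps) + runif(1, 0, 2e-5) * epsHb(eps) +
      rnorm(length(grid), 0, 0.02)
    f <- fitAbsorption(Spectrum(grid, y, "absorbance"), hbTab)
    X0 <- cbind(1, (grid - 550) / 50, ((grid - 550) / 50)^2)
    rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
    expect_lte(f@rss, rss0 + 1e-12)
  }
})

test_that("parameter recovery under multiplicative noise stays within tolerance", {
  # reduced version of the acceptance sweep: mid-range amplitude, 1% noise
  shaped <- makeLampSpectrum(seq(498, 602), seed = 3)
  # peak true absorbance ~30% of the lamp, a typical perfused-tissue level
  aTot <- 0.3 * min(specValues(shaped) /
                      pmax(epsHbO2(resampleExtinction(hbTab, 498:602)),
                           epsHb(resampleExtinction(hbTab, 498:602))))
  bg <- aTot * 3e4 * c(0.05, -0.01, 0.004)
  sVals <- seq(0, 1, by = 0.25)
  errs <- c()
  for (si in seq_along(sVals)) for (sd in 1:6) {
    m <- makeReflectance(sVals[si] * aTot, (1 - sVals[si]) * aTot,
                         bg, shaped, noiseFrac = 0.01,
                         seed = si * 100 + sd, extinction = hbTab)
    f <- fitAbsorption(inferAbsorption(m, shaped, anchorScale = FALSE),
                       hbTab)
    errs <- c(errs, abs(sto2(f) - sVals[si]))
  }
  expect_lte(median(errs), 0.02)
})

test_that("window and point-count preconditions are enforced", {
  short <- Spectrum(seq(500, 540), rep(0.1, 41), "absorbance")
  expect_error(fitAbsorption(short, hbTab), class = "spx_coverage_error")
  sparse <- Spectrum(c(500, 550, 600), c(0.1, 0.2, 0.1), "absorbance")
  expect_error(fitAbsorption(sparse, hbTab), class = "spx_coverage_error")
})
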