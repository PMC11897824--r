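test_that("spectrum writer/reader round-trips values and metadata", {
  s <- Spectrum(seq(500, 600, 1), 1000 + 50 * sin(seq(500, 600, 1) / 20),
                kind = "reflectance",
                meta = list(timestamp_s = -3000, integration_s = 5,
                            site = "hilum", notes = "benching"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectrum(s, path)

  lines <- readLines(path)
  expect_true(startsWith(lines[1], "#"))
  firstData <- lines[which(lines == "wavelength_nm,value") + 1]
  expect_equal(as.numeric(strsplit(firstData, ",")[[1]][1]), 500)

  r <- readSpectrum(path, kind = "reflectance")
  expect_equal(specValues(r), specValues(s), tolerance = 1e-6)
  expect_identical(wavelengths(r), wavelengths(s))
  expect_equal(specMeta(r)$timestamp_s, -3000)
  expect_equal(specMeta(r)$integration_s, 5)
  expect_identical(specMeta(r)$site, "hilum")
  expect_identical(specMeta(r)$notes, "benching")
})

test_that("reader rejects malformed, disordered and negative-count files", {
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,value", "500,10", "500,11", "501,12"), dup)
  expect_error(readSpectrum(dup, "reflectance"), class = "spx_order_error")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,value", "500,-1", "501,2"), neg)
  expect_error(readSpectrum(neg, "reflectance"),
               class = "spx_validation_error")
  # absorbance may be negative
  expect_s4_class(readSpectrum(neg, "absorbance"), "Spectrum")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,value", "500,1,9"), bad)
  expect_error(readSpectrum(bad, "reflectance"), class = "spx_parse_error")

  expect_error(readSpectrum("/nope.csv", "reflectance"),
               class = "spx_file_error")
  # zero-length spectra are rejected at construction, before any write
  expect_error(Spectrum(numeric(0), numeric(0), "reflectance"), "empty")
})

test_that("grid alignment returns identical grids and interpolates the finer spectrum", {
  g <- seq(499, 601, 1)
  a <- Spectrum(g, 1000 + g, kind = "reflectance")
  b <- Spectrum(g, 2000 - g, kind = "reference")
  al <- alignGrids(a, b)
  expect_identical(wavelengths(al$a), wavelengths(al$b))
  expect_identical(specValues(al$a), (1000 + g)[g >= 499 & g <= 601])

  # offset grids: coarser wins, other interpolated; check 3 spot wavelengths
  g2 <- g + 0.1
  b2 <- Spectrum(g2, 2000 - g2, kind = "reference")
  al2 <- alignGrids(a, b2, toleranceNm = 0.5)
  expect_identical(wavelengths(al2$a), wavelengths(al2$b))
  for (wl in c(520, 550, 580)) {
    i <- which(wavelengths(al2$b) == wl)
    # linear data: interpolation is exact
    expect_equal(specValues(al2$b)[i], 2000 - wl, tolerance = 1e-9)
  }

  # disjoint coverage of the haemoglobin window is an error
  expect_error(alignGrids(Spectrum(seq(500, 560), rep(1, 61), "reflectance"),
                          Spectrum(seq(570, 600), rep(1, 31), "reference")),
               class = "spx_alignment_error")
})

test_that("series files round-trip", {
  dir <- withr::local_tempdir()
  ser <- StO2Series(c(-50, 0, 15, 30), c(0.2, 0.9, NA, 0.93),
                    c("ok", "ok", "fit-failed", "ok"))
  p <- file.path(dir, "sto2.csv")
  writeStO2Series(ser, p)
  back <- readStO2Series(p)
  expect_equal(sto2(back), sto2(ser))
  expect_identical(qualityFlags(back), qualityFlags(ser))

  rb <- RBFiSeries(c(0, 300, 600), c(100, 98.5, 2))
  p2 <- file.path(dir, "rbfi.csv")
  writeRBFiSeries(rb, p2)
  expect_equal(rbfi(readRBFiSeries(p2)), rbfi(rb))
})

test_that("invalid series and spectra are refused by validity checks", {
  expect_error(StO2Series(c(0, 0), c(0.5, 0.5)), "strictly increasing")
  expect_error(StO2Series(c(0, 1), c(0.5, 1.5)), "\\[0, 1\\]")
  expect_error(RBFiSeries(c(0, 1), c(-1, 2)), ">= 0")
  expect_error(Spectrum(c(500, 501), c(-1, 1), "reflectance"), ">= 0")
  expect_error(Spectrum(c(300, 500), c(1, 1), "reference"), "within")
})
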