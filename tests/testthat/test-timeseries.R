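test_that("site averaging reproduces the printed per-row table arithmetic", {
  # half-away rounding, including the 0.67475 -> 0.675 half case
  expect_equal(aggregateSites(c(hilum = 0.834, superior = 0.804,
                                lateral = 0.635, inferior = 0.426)), 0.675)
  expect_equal(aggregateSites(c(hilum = 0, superior = 0,
                                lateral = 0.089, inferior = 0.745)), 0.209)
  expect_equal(aggregateSites(c(hilum = 0.3, superior = 0.3,
                                lateral = 0.3, inferior = 0.3)), 0.3)
  # partial rows: mean over the present entries only
  expect_equal(aggregateSites(c(hilum = 0.5, lateral = 0.7)), 0.6)
  expect_error(aggregateSites(numeric(0)), class = "spx_parameter_error")
  expect_error(aggregateSites(c(apex = 0.5)), class = "spx_validation_error")
  # the rounding rule itself: exact decimal halves move away from zero
  expect_equal(roundHalfAway(0.9335, 3), 0.934)
  expect_equal(roundHalfAway(92.5), 93)
  expect_equal(roundHalfAway(-0.0005, 3), -0.001)
})

test_that("wide site tables carry one row per time with an average column", {
  long <- siteTableLong("kidneyA")
  wide <- buildSiteTable(long)
  expect_equal(nrow(wide), 4)
  expect_identical(names(wide),
                   c("time_s", "hilum", "superior", "lateral", "inferior",
                     "average"))
  expect_equal(wide$average[1], 0.675)
})

test_that("phase averages pool individual site values and report integer percentages", {
  # single row per phase with identical values maps to (v, v)
  toy <- data.frame(time_s = c(0, 0, 100, 100), site = rep("hilum", 4),
                    sto2 = rep(0.4, 4))
  expect_equal(unname(phaseAverage(toy, 50)), c(40, 40))
  expect_error(phaseAverage(toy, -1), class = "spx_phase_error")
})

test_that("median smoothing matches the brute-force sliding median and suppresses outliers", {
  s <- StO2Series(1:5, c(0.9, 0.9, 0.1, 0.9, 0.9))
  expect_equal(sto2(medianSmooth(s, 3)), rep(0.9, 5))

  const <- StO2Series(1:7, rep(0.42, 7))
  expect_equal(sto2(medianSmooth(const, 5)), rep(0.42, 7))

  set.seed(12)
  for (rep in 1:25) {
    n <- sample(7:40, 1)
    x <- runif(n)
    ser <- StO2Series(seq_len(n), x)
    sm <- medianSmooth(ser, 5)
    expect_equal(sto2(sm), bruteMedian(x, 5))
    # smoothed values never leave the range of their input window
    expect_true(all(sto2(sm) >= min(x) & sto2(sm) <= max(x)))
  }

  expect_error(medianSmooth(s, 4), class = "spx_parameter_error")
  expect_error(medianSmooth(s, 7), class = "spx_parameter_error")
})

test_that("median smoothing excludes flagged samples from every window", {
  ser <- StO2Series(1:5, c(0.9, 0.9, 0.1, 0.9, 0.9),
                    c("ok", "ok", "ambient-light", "ok", "ok"))
  sm <- medianSmooth(ser, 3)
  expect_equal(sto2(sm)[c(1, 2, 4, 5)], rep(0.9, 4))
  expect_identical(qualityFlags(sm), qualityFlags(ser))
  expect_identical(sampleTimes(sm), sampleTimes(ser))
})

test_that("step-down profiling locates the largest drop and the plateau", {
  res <- stepdownProfile(c(100, 75, 50, 25, 0),
                         c(0.859, 0.819, 0.786, 0.593, 0.595))
  expect_equal(largestDropInterval(res), c(50, 25))
  expect_equal(plateauOnset(res), 25)

  # monotone equal steps: tie broken toward the higher-flow pair
  tie <- stepdownProfile(c(100, 75, 50, 25, 0), c(0.9, 0.8, 0.7, 0.6, 0.5))
  expect_equal(largestDropInterval(tie), c(100, 75))

  expect_error(stepdownProfile(c(100, 50), c(0.9, 0.5)),
               class = "spx_profile_error")
  expect_error(stepdownProfile(c(100, 75, 75, 0), c(0.9, 0.8, 0.7, 0.6)),
               class = "spx_validation_error")
})

test_that("abrupt-drop detection requires synchronized StO2 and RBFi drops", {
  t <- seq(0, 3600, by = 15)
  flatS <- StO2Series(t, rep(0.95, length(t)))
  flatR <- RBFiSeries(t, rep(100, length(t)))
  expect_identical(eventKind(detectAbruptDrop(flatS, flatR)), "none")

  dropAt <- 1800
  sv <- ifelse(t < dropAt, 0.95, 0.90)
  rv <- ifelse(t < dropAt, 100, 20)
  ev <- detectAbruptDrop(StO2Series(t, sv), RBFiSeries(t, rv))
  expect_identical(eventKind(ev), "decompensation")
  b <- eventBounds(ev)
  expect_lte(b[["start"]], dropAt)
  expect_gte(b[["end"]], dropAt)

  # StO2 drop without an RBFi drop: no event
  expect_identical(eventKind(detectAbruptDrop(StO2Series(t, sv), flatR)),
                   "none")
  # RBFi drop without an StO2 drop: no event
  expect_identical(eventKind(detectAbruptDrop(flatS, RBFiSeries(t, rv))),
                   "none")

  expect_error(detectAbruptDrop(StO2Series(1:10 / 10, rep(0.9, 10)),
                                RBFiSeries(100 + 1:10, rep(1, 10))),
               class = "spx_alignment_error")
})
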