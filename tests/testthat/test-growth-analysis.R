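test_that("exact exponential and linear series are fitted perfectly", {
  t <- seq(0, 26, by = 2)
  fe <- fitSingleCellGrowth(t, 2 * exp(0.0274 * t))
  expect_equal(fe$rate_per_min, 0.0274, tolerance = 1e-10)
  expect_equal(fe$r2_exponential, 1, tolerance = 1e-10)
  expect_lt(fe$r2_linear, 1)
  fl <- fitSingleCellGrowth(t, 2 + 0.07 * t)
  expect_equal(fl$r2_linear, 1, tolerance = 1e-10)
  expect_lt(fl$r2_exponential, 1)
  expect_error(fitSingleCellGrowth(c(0, 1), c(2, 3)), "3 distinct")
  expect_error(fitSingleCellGrowth(t, -2 * exp(0.0274 * t)), "positive")
})

test_that("exponential fits beat linear fits on noisy exponential cells", {
  set.seed(14)
  t <- seq(0, 25, by = 1)
  res <- t(vapply(seq_len(300L), function(i) {
    v <- rnorm(1, 0.0274, 0.0022)
    l <- 2 * exp(v * t) * (1 + rnorm(length(t), 0, 0.01))
    f <- fitSingleCellGrowth(t, l)
    c(f$r2_exponential, f$r2_linear)
  }, numeric(2L)))
  expect_gt(median(res[, 1L]), median(res[, 2L]))
})

test_that("the increment curve is proportional for exponential growth", {
  tr <- sizerSparseTracks()
  cv <- incrementCurve(tr, binWidth = 0.15)
  ## mean increment = l (e^{v dt} - 1): slope through the origin
  expect_equal(cv$propSlope, exp(0.0274 * cv$dt) - 1, tolerance = 0.02)
  expect_lt(abs(cv$intercept), 0.1 * cv$propSlope * 3)  # near-zero intercept
  pop <- cv$bins$count > 0
  expect_true(all(is.finite(cv$bins$sem_um[pop]) | cv$bins$count[pop] < 2))
})

test_that("the exponential range boundary is detected within one bin", {
  law <- growthLaw(0.0274, xMin = 2.3, xMax = 5.3,
                   capBelow = "none", capAbove = "constant")
  cfg <- simConfig("sizer",
                   divisionRate = tabulateDivisionRate(
                     function(x) 0.02 * (x / 3.6)^8, "size", 12),
                   growthLaw = law, topology = "sparse_tree",
                   nChannels = 300L, seed = 9L, rateCV = 0, septumCV = 0.04)
  tr <- simulateMotherMachine(cfg)
  cv <- incrementCurve(tr, binWidth = 0.15, fitRange = c(2.8, 4.6))
  expect_lt(abs(cv$xMax - 5.3), 0.15)
})

test_that("degenerate increment input errors cleanly", {
  tiny <- data.frame(cell_id = 1L, parent_id = NA, time_min = c(0, 2),
                     length_um = c(2, 2.1))
  expect_error(incrementCurve(tiny, binWidth = 0.2, fitRange = c(5, 6)),
               "no populated bins")
})

test_that("noise summary recovers the generator CVs", {
  cyc <- extractCycles(sizerFullTracks(), discardBefore = 100)
  ns <- noiseSummary(cyc)
  expect_gt(ns$rateCV, 0.07); expect_lt(ns$rateCV, 0.09)
  expect_gt(ns$septumCV, 0.035); expect_lt(ns$septumCV, 0.045)
  expect_equal(gridIntegral(ns$rateDensity), 1, tolerance = 1e-3)
  ## perfectly symmetric division: zero septum CV, no density
  cyc0 <- cyc
  cyc0$septum_ratio <- ifelse(is.na(cyc0$septum_ratio), NA, 0.5)
  ns0 <- noiseSummary(cyc0)
  expect_equal(ns0$septumCV, 0)
  expect_error(noiseSummary(cyc[1:10, ]), "too few")
})
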