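test_that("the distance metric satisfies its defining identities", {
  g <- sizecontrol:::cellCenters(10, 2^7)
  f <- densityGrid(dnorm(g, 4, 0.8), size = g)
  expect_equal(distancePct(densityDistance(f, f)), 0)
  zero <- densityGrid(rep(0, length(g)), size = g, normalize = FALSE)
  expect_equal(distancePct(densityDistance(f, zero)), 100)
  other <- densityGrid(dnorm(g, 5, 0.8), size = g)
  expect_error(densityDistance(f, densityGrid(dnorm(g[-1], 4, 0.8),
                                              size = g[-1])), "grids differ")
  expect_error(densityDistance(f, kde2d(rnorm(50, 20, 3), rnorm(50, 4, .5))),
               "axes differ")
})

test_that("D increases monotonically along a mixture path", {
  g <- sizecontrol:::cellCenters(10, 2^7)
  f <- densityGrid(dnorm(g, 4, 0.8), size = g)
  h <- densityGrid(dnorm(g, 6, 1.2), size = g)
  eps <- seq(0, 1, by = 0.1)
  ds <- sapply(eps, function(e) {
    mix <- densityGrid((1 - e) * densityValues(f) + e * densityValues(h),
                       size = g, normalize = FALSE)
    distancePct(densityDistance(f, mix))
  })
  expect_true(all(diff(ds) > 0))
})

test_that("correlation diagnostics separate timer from sizer control", {
  sizer <- correlationDiagnostic(sizerCycles2e4()[1:10000, ], nPerm = 200L)
  expect_lt(sizer$r, -0.3)
  expect_lt(sizer$p, 0.05)
  timer <- correlationDiagnostic(timerCycles2e4()[1:10000, ], nPerm = 200L)
  expect_lt(abs(timer$r), 0.05)
})

test_that("a deterministic sizer gives the monotone-transform correlation", {
  set.seed(9)
  xb <- rlnorm(500L, log(2), 0.15)
  v <- 0.0274
  cyc <- data.frame(cell_id = 1:500, birth_time_min = 0, birth_size_um = xb,
                    division_time_min = log(4 / xb) / v,
                    division_size_um = 4, division_age_min = log(4 / xb) / v,
                    growth_rate_per_min = v, septum_ratio = 0.5,
                    complete = TRUE)
  res <- correlationDiagnostic(cyc, nPerm = 200L)
  expect_equal(res$r, cor(log(4 / xb) / v, xb))
  expect_lt(res$r, 0)
  cyc$birth_size_um <- 2
  expect_error(correlationDiagnostic(cyc, nPerm = 10L), "constant column")
})

test_that("evaluateModels identifies the generating control law", {
  repS <- sizerEvalReport()
  expect_equal(preferredModel(repS), "sizer")
  expect_lt(repS@dSize@pct, repS@dAge@pct)
  repT <- timerEvalReport()
  expect_equal(preferredModel(repT), "timer")
  expect_lt(repT@dAge@pct, repT@dSize@pct)
  ## determinism: identical input and seed give identical distances
  rep2 <- evaluateModels(sizerSparseTracks(), generationWindow = c(10L, 50L))
  expect_identical(distancePct(rep2), distancePct(repS))
  expect_identical(rep2@correlation, repS@correlation)
})

test_that("evaluateModels refuses undersized datasets", {
  few <- simulateMotherMachine(simConfig("sizer", topology = "sparse_tree",
                                         nChannels = 5L, generations = 6L,
                                         seed = 2L))
  expect_error(evaluateModels(few), "insufficient cycles")
})

test_that("robustness scans start at zero and reject bad input", {
  expect_error(robustnessScan(sizerHazard(), growthLaw(0.0274), "septum",
                              cvList = c(0.3, 0.1)), "sorted")
  sc <- robustnessScan(sizerHazard(), growthLaw(0.0274), "septum",
                       cvList = c(0, 0.1))
  expect_equal(sc$distance_pct[1L], 0)
  expect_gt(sc$distance_pct[2L], 0)
})
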