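test_that("kde1d respects symmetry and normalization", {
  g <- seq(0.025, 8, length.out = 2^7)
  d <- kde1d(c(2, 4), grid = g, bw = 0.5)
  expect_equal(gridIntegral(d), 1, tolerance = 1e-3)
  ## symmetric two-point sample: mean of the density sits at the midpoint
  m <- sizecontrol:::trapz(g, g * densityValues(d))
  expect_equal(m, 3, tolerance = 1e-3)
})

test_that("kde1d is L1-consistent for an exponential sample", {
  set.seed(2)
  x <- rexp(10000L)
  g <- sizecontrol:::cellCenters(max(x), 2^7)
  d <- kde1d(x, grid = g, axis = "age")
  l1 <- sizecontrol:::trapz(g, abs(densityValues(d) - dexp(g)))
  expect_lt(l1, 0.05)
})

test_that("degenerate samples are refused", {
  expect_error(kde1d(rep(2, 100L)), "constant")
  expect_error(kde1d(numeric(0)), "at least 2")
  expect_error(kde2d(rep(1, 50L), rnorm(50L, 4)), "degenerate")
})

test_that("kde2d localizes a shifted Gaussian cloud and normalizes", {
  set.seed(3)
  a <- rnorm(10000L, 30, 3)
  x <- rnorm(10000L, 4, 0.4)
  d <- kde2d(a, x, bwAge = 2, bwSize = 0.3)
  expect_equal(gridIntegral(d), 1, tolerance = 1e-3)
  v <- densityValues(d)
  ij <- which(v == max(v), arr.ind = TRUE)
  ag <- gridAxis(d, "age"); xg <- gridAxis(d, "size")
  expect_lt(abs(ag[ij[1L]] - 30), diff(ag[1:2]) * 1.5)
  expect_lt(abs(xg[ij[2L]] - 4), diff(xg[1:2]) * 1.5)
})

test_that("the estimator depends only on the empirical measure", {
  set.seed(4)
  a <- runif(300L, 10, 40); x <- runif(300L, 2, 6)
  g1 <- kde2d(a, x, bwAge = 2, bwSize = 0.3)
  g2 <- kde2d(rep(a, 2L), rep(x, 2L), bwAge = 2, bwSize = 0.3)
  expect_equal(densityValues(g1), densityValues(g2), tolerance = 1e-12)
})

test_that("binned and exact kde2d paths agree", {
  set.seed(5)
  n <- 30000L  # above the binned-path threshold
  a <- rnorm(n, 25, 6); a <- a[a > 0]
  x <- rnorm(length(a), 4, 0.7)
  ag <- sizecontrol:::cellCenters(max(a), 2^7)
  xg <- sizecontrol:::cellCenters(max(x), 2^7)
  fast <- kde2d(a, x, ageGrid = ag, sizeGrid = xg, bwAge = 2, bwSize = 0.2)
  idx <- seq_len(15000L)  # exact path on a subsample, same points twice
  exact <- kde2d(a[idx], x[idx], ageGrid = ag, sizeGrid = xg, bwAge = 2,
                 bwSize = 0.2)
  fast2 <- kde2d(rep(a[idx], 2L), rep(x[idx], 2L), ageGrid = ag,
                 sizeGrid = xg, bwAge = 2, bwSize = 0.2)
  expect_lt(distancePct(densityDistance(exact, fast2)), 0.5)
})

test_that("smoothDensity reproduces kernel-smoothed truth", {
  g <- sizecontrol:::cellCenters(10, 2^7)
  f <- densityGrid(dnorm(g, 5, 0.8), size = g)
  sm <- smoothDensity(f, c(size = 0.6))
  expect_equal(gridIntegral(sm), 1, tolerance = 1e-6)
  ## Gaussian convolved with Gaussian stays Gaussian with summed variances
  truth <- dnorm(g, 5, sqrt(0.8^2 + 0.6^2))
  truth <- truth / sizecontrol:::trapz(g, truth)
  expect_lt(max(abs(densityValues(sm) - truth)), 1e-3)
})
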