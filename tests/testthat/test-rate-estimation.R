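mkAgeCycles <- function(ages) {
  data.frame(cell_id = seq_along(ages), birth_time_min = 0,
             birth_size_um = 2, division_time_min = ages,
             division_size_um = 4, division_age_min = ages,
             growth_rate_per_min = 0.0274, septum_ratio = 0.5,
             complete = TRUE)
}

test_that("the age hazard of exponential lifetimes is recovered", {
  set.seed(6)
  b <- 0.05
  ages <- rexp(20000L, b)
  Bh <- estimateAgeRate(mkAgeCycles(ages))
  g <- rateGrid(Bh)
  qs <- quantile(ages, c(0.05, 0.95))
  m <- g >= qs[1L] & g <= qs[2L] & reliableSupport(Bh)
  expect_true(all(abs(rateValues(Bh)[m] - b) / b < 0.15))
})

test_that("a near-deterministic timer concentrates the hazard", {
  set.seed(7)
  ages <- rnorm(5000L, 30, 0.4)
  Bh <- estimateAgeRate(mkAgeCycles(ages))
  g <- rateGrid(Bh)
  expect_lt(max(rateValues(Bh)[g < 27]), 0.01)
  expect_gt(max(rateValues(Bh)[g >= 27 & g <= 32]), 0.3)
})

test_that("tiny samples still produce an estimate, with warnings", {
  set.seed(8)
  expect_warning(Bh <- estimateAgeRate(mkAgeCycles(rexp(10L, 0.05))),
                 "complete cycles")
  expect_true(is(Bh, "DivisionRate"))
  expect_lt(mean(reliableSupport(Bh)), 1)
})

test_that("the sizer hazard is recovered within 15% on the central range", {
  cyc <- sizerCycles2e4()
  Bh <- estimateSizeRate(cyc, growthLaw(0.0274))
  err <- relL2Central(Bh, function(x) 0.02 * (x / 3)^8,
                      cyc$division_size_um[cyc$complete])
  expect_lt(err, 0.15)
  expect_true(all(rateValues(Bh) >= 0))
  ## zero below the smallest birth size
  expect_true(all(rateValues(Bh)[rateGrid(Bh) < min(cyc$birth_size_um)] == 0))
})

test_that("a hard size threshold yields the deterministic-sizer picture", {
  Bs <- tabulateDivisionRate(function(x) 50 * (x / 4)^120, "size", 8)
  cyc <- simulateCycles(simConfig("sizer", divisionRate = Bs,
                                  topology = "sparse_tree", nChannels = 200L,
                                  seed = 5L, rateCV = 0, septumCV = 0.04),
                        5000L)
  Bh <- estimateSizeRate(cyc, growthLaw(0.0274))
  g <- rateGrid(Bh)
  expect_lt(max(rateValues(Bh)[g < 3.5]), 0.05)
  expect_gt(max(rateValues(Bh)[g >= 3.5 & g <= 4.5]), 0.5)
})

test_that("relabeling all sizes by 2x leaves the time hazard invariant", {
  cyc <- sizerCycles2e4()[seq_len(10000L), ]
  law <- growthLaw(0.03)
  B1 <- estimateSizeRate(cyc, law)
  cyc2 <- cyc
  cyc2$birth_size_um <- 2 * cyc$birth_size_um
  cyc2$division_size_um <- 2 * cyc$division_size_um
  B2 <- estimateSizeRate(cyc2, law)
  ## with v(x) = vx unchanged, doubling sizes is a pure relabeling:
  ## B'(2x) = B(x) on the reliable support
  g <- rateGrid(B1)
  m <- reliableSupport(B1) & g > quantile(cyc$division_size_um, 0.1) &
    g < quantile(cyc$division_size_um, 0.9)
  b2At2x <- approx(rateGrid(B2), rateValues(B2), xout = 2 * g[m])$y
  expect_lt(sqrt(sum((b2At2x - rateValues(B1)[m])^2) /
                 sum(rateValues(B1)[m]^2)), 0.05)
})

test_that("estimation error shrinks with sample size", {
  errAt <- function(n, seed) {
    cyc <- simulateCycles(simConfig("sizer", topology = "sparse_tree",
                                    nChannels = 250L, seed = seed), n)
    Bh <- estimateSizeRate(cyc, growthLaw(0.0274), minCycles = 0L)
    relL2Central(Bh, function(x) 0.02 * (x / 3)^8, cyc$division_size_um)
  }
  meds <- sapply(c(1000L, 10000L), function(n)
    median(sapply(1:5, function(r) errAt(n, 300L + r))))
  expect_lt(meds[2L], meds[1L])
})

test_that("estimator preconditions are enforced", {
  cyc <- mkAgeCycles(rexp(200L, 0.05))
  cyc$complete <- FALSE
  expect_error(estimateAgeRate(cyc), "no complete cycles")
  law0 <- growthLaw(0.03, xMin = 1e-4, xMax = 2e-4,
                    capBelow = "polynomial", capAbove = "polynomial",
                    polyBelow = 0, polyAbove = 0)
  cycS <- sizerCycles2e4()[1:500, ]
  expect_error(suppressWarnings(estimateSizeRate(cycS, law0)), "zero on the observed")
})
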