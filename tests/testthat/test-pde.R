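test_that("solutions are positive, normalized and reproducible", {
  sol <- solveStable("size", sizerHazard(), growthLaw(0.0274), xMax = 10)
  expect_true(all(densityValues(sol) >= 0))
  expect_equal(gridIntegral(sol@density), 1, tolerance = 1e-6)
  expect_true(sol@converged)
  expect_lt(sol@residual, 1e-8)
  sol2 <- solveStable("size", sizerHazard(), growthLaw(0.0274), xMax = 10)
  expect_identical(densityValues(sol), densityValues(sol2))
})

test_that("sparse-tree renewal gives a critical population (lambda ~ 0)", {
  sol <- solveStable("size", sizerHazard(), growthLaw(0.0274), xMax = 10,
                     topology = "sparse_tree")
  expect_lt(abs(malthusCoefficient(sol)), 1e-6)
  sol2 <- solveStable("age", timerHazard(), cappedLaw(), xMax = 12,
                      topology = "sparse_tree")
  expect_lt(abs(malthusCoefficient(sol2)), 1e-4)
})

test_that("the noise-extended solvers reduce exactly to the Size Model", {
  base <- solveStable("size", sizerHazard(), growthLaw(0.0274), xMax = 10)
  gv <- solveGrowthVariability(sizerHazard(), growthLaw(0.0274), cv = 0,
                               xMax = 10)
  sn <- solveSeptumNoise(sizerHazard(), growthLaw(0.0274), cv = 0, xMax = 10)
  expect_lt(distancePct(densityDistance(sizeMarginal(base), sizeMarginal(gv))), 0.5)
  expect_lt(distancePct(densityDistance(sizeMarginal(base), sizeMarginal(sn))), 0.5)
})

test_that("distinct initializations converge to the same distribution", {
  base <- solveStable("size", sizerHazard(), growthLaw(0.0274), xMax = 10)
  alt <- solveStable("size", sizerHazard(), growthLaw(0.0274), xMax = 10,
                     init = rev(seq(0.1, 1, length.out = 2^7)) + 0.2)
  expect_lt(distancePct(densityDistance(sizeMarginal(base),
                                        sizeMarginal(alt))) / 100, 1e-3)
})

test_that("grid refinement changes the solution at first order only", {
  base <- solveStable("size", sizerHazard(), growthLaw(0.0274), xMax = 10)
  ref <- solveStable("size", sizerHazard(), growthLaw(0.0274), xMax = 10,
                     nSize = 2L^8L)
  expect_lt(abs(malthusCoefficient(ref) - malthusCoefficient(base)) /
            malthusCoefficient(base), 0.005)
  g1 <- gridAxis(sizeMarginal(base), "size")
  vi <- approx(gridAxis(sizeMarginal(ref), "size"),
               densityValues(sizeMarginal(ref)), xout = g1, rule = 2L)$y
  expect_lt(distancePct(densityDistance(densityGrid(densityValues(sizeMarginal(base)), size = g1),
                                        densityGrid(vi, size = g1))), 2)
  ## two-dimensional model: constant-hazard eigenvalue is grid-insensitive
  b <- 0.0347
  Ba <- divisionRate("age", seq(0, 120, length.out = 64), rep(b, 64))
  a1 <- solveStable("age", Ba, cappedLaw(), xMax = 12)
  a2 <- solveStable("age", Ba, cappedLaw(), xMax = 12, nAge = 2L^8L,
                    nSize = 2L^8L)
  expect_lt(abs(malthusCoefficient(a2) - malthusCoefficient(a1)) /
            malthusCoefficient(a1), 0.005)
})

test_that("timer with uncapped exponential growth reaches no stable state", {
  err <- tryCatch(
    solveStable("age", timerHazard(), growthLaw(0.0274), xMax = 12,
                maxIter = 4000L),
    error = identity)
  expect_s3_class(err, "sizecontrol_no_convergence")
  expect_match(conditionMessage(err), "no stable distribution")
})

test_that("septum kernels are validated", {
  expect_warning(
    solveSeptumNoise(sizerHazard(), growthLaw(0.0274), thetas = c(0.4, 0.45),
                     thetaW = c(0.3, 0.7), xMax = 10, maxIter = 200L) |>
      tryCatch(error = function(e) NULL),
    "asymmetric")
  expect_error(
    solveSeptumNoise(sizerHazard(), growthLaw(0.0274), thetas = c(0.03, 0.97),
                     thetaW = c(0.5, 0.5), xMax = 10),
    "degenerate daughters")
})

test_that("growth-rate variability perturbs the size distribution progressively", {
  base <- solveGrowthVariability(sizerHazard(), growthLaw(0.0274), cv = 0,
                                 xMax = 10)
  lo <- solveGrowthVariability(sizerHazard(), growthLaw(0.0274), cv = 0.1,
                               xMax = 10)
  hi <- solveGrowthVariability(sizerHazard(), growthLaw(0.0274), cv = 0.4,
                               xMax = 10)
  dLo <- distancePct(densityDistance(sizeMarginal(base), sizeMarginal(lo)))
  dHi <- distancePct(densityDistance(sizeMarginal(base), sizeMarginal(hi)))
  expect_gt(dLo, 0)
  expect_gt(dHi, dLo)
})
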