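test_that("constant-hazard timer lifetimes are exponential", {
  b <- 0.04
  cfg <- simConfig("timer", divisionRate = divisionRate("age", c(0, 400), c(b, b)),
                   growthLaw = cappedLaw(), topology = "sparse_tree",
                   nChannels = 500L, seed = 17L, rateCV = 0, septumCV = 0)
  cyc <- simulateCycles(cfg, 10000L)
  ages <- cyc$division_age_min
  se <- (1 / b) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - 1 / b), 3 * se)
  ## exponential also in spread: CV of an exponential is 1
  expect_equal(sd(ages) / mean(ages), 1, tolerance = 0.05)
})

test_that("a steep sizer threshold pins division and birth sizes", {
  Bs <- tabulateDivisionRate(function(x) 50 * (x / 4)^120, "size", 8)
  cfg <- simConfig("sizer", divisionRate = Bs, topology = "sparse_tree",
                   nChannels = 100L, generations = 30L, seed = 5L,
                   rateCV = 0, septumCV = 0)
  cyc <- simulateCycles(cfg, 2000L)
  ## all divisions in a narrow band just below the 4 um threshold
  expect_true(all(cyc$division_size_um > 3.5 & cyc$division_size_um < 4.1))
  expect_lt(diff(quantile(cyc$division_size_um, c(0.01, 0.99))), 0.4)
  xb <- cyc$birth_size_um[cyc$generation > 1]
  expect_true(all(xb > 1.75 & xb < 2.05))  # exactly half the division size
})

test_that("identical configurations reproduce bit-identical tables", {
  cfg <- simConfig("sizer", topology = "full_tree", duration = 120,
                   nInitial = 4L, seed = 99L)
  t1 <- simulatePopulation(cfg)
  t2 <- simulatePopulation(cfg)
  expect_identical(t1$length_um, t2$length_um)
  expect_identical(t1$time_min, t2$time_min)
  cfgB <- cfg; cfgB@seed <- 100L
  t3 <- simulatePopulation(cfgB)
  expect_false(identical(t1$length_um, t3$length_um))
  m1 <- simulateMotherMachine(simConfig("sizer", topology = "sparse_tree",
                                        nChannels = 30L, generations = 10L,
                                        seed = 7L))
  m2 <- simulateMotherMachine(simConfig("sizer", topology = "sparse_tree",
                                        nChannels = 30L, generations = 10L,
                                        seed = 7L))
  expect_identical(m1, m2)
})

test_that("division partitions the mother's size exactly (pre-noise)", {
  tr <- sizerFullTracks()
  cells <- attr(tr, "cells")
  kids <- cells[!is.na(cells$parent_id), ]
  sums <- tapply(kids$birth_size, kids$parent_id, sum)
  mothers <- cells$division_size[match(as.numeric(names(sums)), cells$cell_id)]
  expect_lt(max(abs(sums - mothers)), 1e-12)
  ## extracted septum ratios of the two daughters of one mother sum to 1
  cyc <- extractCycles(tr)
  parentOf <- cells$parent_id[match(cyc$cell_id, cells$cell_id)]
  ok <- !is.na(parentOf) & is.finite(cyc$septum_ratio)
  ratioSums <- tapply(cyc$septum_ratio[ok], parentOf[ok], sum)
  ratioSums <- ratioSums[!is.na(ratioSums)]
  expect_lt(max(abs(ratioSums - 1)), 1e-9)
})

test_that("full-tree counts satisfy cells = 2 divisions + founders", {
  cfg <- simConfig("sizer", topology = "full_tree", duration = 150,
                   nInitial = 3L, seed = 12L)
  tr <- simulatePopulation(cfg)
  cells <- attr(tr, "cells")
  expect_equal(nrow(cells), 2L * sum(cells$complete) + 3L)
})

test_that("mother machine follows one lineage per channel", {
  cfg <- simConfig("sizer", topology = "sparse_tree", nChannels = 100L,
                   generations = 40L, seed = 8L)
  tr <- simulateMotherMachine(cfg)
  cells <- attr(tr, "cells")
  expect_equal(sum(cells$complete), 100L * 40L)     # ~4000 complete cycles
  expect_equal(length(unique(cells$channel)), 100L) # concurrent lineages
  ## along a lineage, birth size = retained fraction x previous division size
  ch1 <- cells[cells$channel == 1L, ]
  ch1 <- ch1[order(ch1$generation), ]
  g <- 2:nrow(ch1)
  expect_equal(ch1$birth_size[g],
               ch1$septum_ratio[g] * ch1$division_size[g - 1L],
               tolerance = 1e-12)
})

test_that("sparse and full trees draw lifetimes from the same law", {
  b <- 1 / 26
  Bc <- divisionRate("age", c(0, 200), c(b, b))
  c1 <- simulateCycles(simConfig("timer", divisionRate = Bc,
                                 growthLaw = cappedLaw(),
                                 topology = "sparse_tree", nChannels = 250L,
                                 seed = 1L), 5000L)
  cfg2 <- simConfig("timer", divisionRate = Bc, growthLaw = cappedLaw(),
                    topology = "full_tree", duration = 260, nInitial = 4L,
                    seed = 2L)
  c2 <- extractCycles(simulatePopulation(cfg2))
  ## compare against early-born full-tree cycles (free of end-of-run
  ## censoring: survival past the remaining 130 min is ~e^-5)
  sel <- c2$complete & c2$birth_time_min < 130
  ks <- suppressWarnings(ks.test(c1$division_age_min, c2$division_age_min[sel]))
  expect_gt(ks$p.value, 0.01)
})

test_that("the population cap errors with a partial-output flag", {
  cfg <- simConfig("sizer", topology = "full_tree", duration = 400,
                   nInitial = 4L, seed = 1L, maxCells = 500L)
  err <- tryCatch(simulatePopulation(cfg), error = identity)
  expect_s3_class(err, "sizecontrol_population_cap")
  expect_true(is.data.frame(err$partial))
  expect_gt(nrow(err$partial), 0L)
})

test_that("an exhausted hazard raises a divergent-lifetime error", {
  B0 <- divisionRate("age", c(0, 5), c(0.001, 0.001), extrapolation = "zero")
  cfg <- simConfig("timer", divisionRate = B0, growthLaw = cappedLaw(),
                   topology = "sparse_tree", nChannels = 10L,
                   generations = 2L, seed = 3L)
  expect_error(simulateCycles(cfg, 20L), "divergent lifetime")
})
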