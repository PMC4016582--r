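#' @include distance.R pde.R rate-estimation.R growth-analysis.R measurement.R
NULL

#' Correlation between division age and birth size
#'
#' Under pure timer control the age at division is independent of the size
#' at birth, so their correlation vanishes; under sizer control with
#' exponential growth, cells born large need less time to reach dividing
#' sizes, producing a marked negative correlation (about -0.5 in the
#' reference datasets). The p-value is obtained by a seeded permutation test
#' rather than a parametric formula.
#'
#' @param cycles cycle `data.frame`; needs >= 30 complete cycles.
#' @param nPerm number of permutations.
#' @param seed RNG seed for the permutation test.
#' @return list with `r` (Pearson correlation) and `p` (two-sided
#'   permutation p-value).
#' @export
correlationDiagnostic <- function(cycles, nPerm = 10000L, seed = 1L) {
  cc <- cycles[cycles$complete, , drop = FALSE]
  a <- cc$division_age_min
  x <- cc$birth_size_um
  keep <- is.finite(a) & is.finite(x)
  a <- a[keep]; x <- x[keep]
  if (length(a) < 30L) stopf("need >= 30 complete cycles, have %d", length(a))
  if (var(a) == 0 || var(x) == 0) stopf("constant column: correlation undefined")
  r <- cor(a, x)
  set.seed(seed)
  ac <- a - mean(a); xc <- x - mean(x)
  denom <- sqrt(sum(ac^2) * sum(xc^2))
  exceed <- 0L
  for (i in seq_len(nPerm)) {
    rp <- sum(ac[sample.int(length(ac))] * xc) / denom
    if (abs(rp) >= abs(r)) exceed <- exceed + 1L
  }
  list(r = r, p = (exceed + 1) / (nPerm + 1))
}

## Cubic interpolation of the increment curve, converted to a speed (um/min),
## used as the out-of-range growth cap for the Age Model fit.
fitIncrementPolynomial <- function(curve) {
  b <- curve$bins
  ok <- b$count >= 1L & is.finite(b$mean_increment_um)
  x <- b$bin_center_um[ok]
  y <- b$mean_increment_um[ok] / curve$dt
  w <- b$count[ok]
  X <- cbind(1, x, x^2, x^3)
  as.numeric(solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), y * sqrt(w))))
}

#' Fit and compare the timer and sizer models on tracking data
#'
#' The full discrimination pipeline: extract cycles, characterize single-cell
#' growth (mean exponential rate, exponential size range, increment-curve
#' polynomial for the out-of-range growth caps), estimate the age- and
#' size-indexed division rates, reconstruct the stable age-size distribution
#' under each model by solving the age-and-size structured equation, and
#' measure each reconstruction's distance from the empirical age-size
#' distribution (kernel estimate of the occupation measure: every cell at
#' every time step). The Age Model (timer) runs with the capped growth law;
#' the Size Model (sizer) runs with pure exponential growth, mirroring the
#' reference analysis.
#'
#' @param tracks a TrackTable `data.frame`.
#' @param discardBefore,generationWindow passed to [extractCycles()].
#' @param topology `"full_tree"` or `"sparse_tree"`; default read from the
#'   simulation attributes, else `"full_tree"`.
#' @param nGrid grid size per axis (default 2^7).
#' @param tol,maxIter solver controls.
#' @param nPerm permutations for the correlation test.
#' @param seed seed for the permutation test.
#' @param minCycles minimum complete cycles (error below).
#' @return a [FitReport].
#' @export
evaluateModels <- function(tracks, discardBefore = 0, generationWindow = NULL,
                           topology = NULL, nGrid = 2L^7L, tol = 1e-8,
                           maxIter = 60000L, nPerm = 2000L, seed = 1L,
                           minCycles = 100L) {
  if (is.null(topology)) {
    cfg <- attr(tracks, "config")
    topology <- if (!is.null(cfg)) cfg@topology else "full_tree"
  }
  cycles <- extractCycles(tracks, discardBefore = discardBefore,
                          generationWindow = generationWindow)
  nC <- sum(cycles$complete)
  if (nC < minCycles)
    stopf("insufficient cycles: %d complete (need >= %d)", nC, minCycles)
  ## occupation measure (ages and sizes of every retained cell at every step)
  occ <- occupationMeasure(tracks, discardBefore, generationWindow)
  aMax <- max(occ$age); xMax <- max(occ$size)
  ageGrid <- cellCenters(aMax, nGrid)
  sizeGrid <- cellCenters(xMax, nGrid)
  ## growth characterization
  vhat <- mean(cycles$growth_rate_per_min[cycles$complete &
                                          is.finite(cycles$growth_rate_per_min)])
  curve <- incrementCurve(tracks)
  poly <- fitIncrementPolynomial(curve)
  lawSizer <- growthLaw(vhat)
  lawTimer <- growthLaw(vhat, xMin = curve$xMin, xMax = curve$xMax,
                        capBelow = "polynomial", capAbove = "polynomial",
                        polyBelow = poly, polyAbove = poly, clampZero = TRUE)
  ## division rates
  rateAge <- estimateAgeRate(cycles, grid = ageGrid)
  rateSize <- estimateSizeRate(cycles, lawSizer, grid = sizeGrid)
  ## stable distributions under each restriction
  timerFit <- solveStable("age_size", rateAge, lawTimer, aMax = aMax,
                          xMax = xMax, nAge = nGrid, nSize = nGrid,
                          topology = topology, tol = tol, maxIter = maxIter)
  sizerFit <- solveStable("age_size", rateSize, lawSizer, aMax = aMax,
                          xMax = xMax, nAge = nGrid, nSize = nGrid,
                          topology = topology, tol = tol, maxIter = maxIter)
  ## age observations live on the acquisition lattice: floor the age
  ## bandwidth at the frame interval to avoid per-frame humps
  empirical <- kde2d(occ$age, occ$size, ageGrid = ageGrid, sizeGrid = sizeGrid,
                     bwAge = max(bw.nrd0(occ$age), occ$step),
                     weights = occ$weight)
  dAge <- densityDistance(empirical, timerFit)
  dSize <- densityDistance(empirical, sizerFit)
  corr <- correlationDiagnostic(cycles, nPerm = nPerm, seed = seed)
  new("FitReport", dAge = dAge, dSize = dSize,
      correlation = corr$r, correlationP = corr$p,
      rateAge = rateAge, rateSize = rateSize, growthRate = vhat,
      growthLawTimer = lawTimer, empirical = empirical,
      timerFit = timerFit, sizerFit = sizerFit,
      preferred = if (dAge@pct < dSize@pct) "timer" else "sizer",
      nCycles = as.integer(nC), seed = as.integer(seed))
}

#' Occupation measure of a track table
#'
#' The (age, size) of every cell at every retained time step — the empirical
#' counterpart of the stable age-size distribution. Each cell's first frame
#' (its birth observation) is assigned weight 1/2: per-cell frame sequences
#' sample the cycle from age 0 up to, but excluding, division, and the
#' half-weight turns that one-sided sum into a trapezoidal one, removing the
#' systematic overweighting of birth ages and birth sizes.
#'
#' @param tracks a TrackTable `data.frame`.
#' @param discardBefore,generationWindow observation filters, as in
#'   [extractCycles()].
#' @return list with `age`, `size`, `weight` (one entry per retained frame)
#'   and `step` (the median acquisition interval, min).
#' @export
occupationMeasure <- function(tracks, discardBefore = 0, generationWindow = NULL) {
  dt <- as.data.table(tracks)
  setorder(dt, cell_id, time_min)
  dt[, age := time_min - time_min[1L], by = cell_id]
  keep <- dt$time_min >= discardBefore
  if (!is.null(generationWindow)) {
    per <- dt[, .(parent_id = parent_id[1L]), by = cell_id]
    gen <- assignGenerations(per$cell_id, per$parent_id)
    g <- gen[match(dt$cell_id, per$cell_id)]
    keep <- keep & !is.na(g) & g > generationWindow[1L] & g <= generationWindow[2L]
  }
  step <- stats::median(dt[, diff(time_min), by = cell_id]$V1)
  list(age = dt$age[keep], size = dt$length_um[keep],
       weight = ifelse(dt$age[keep] == 0, 0.5, 1), step = step)
}

#' @rdname distancePct
setMethod("distancePct", "FitReport", function(x)
  c(age = x@dAge@pct, size = x@dSize@pct))

#' @rdname distancePct
setMethod("preferredModel", "FitReport", function(x) x@preferred)

setMethod("show", "FitReport", function(object) {
  cat("FitReport (timer vs sizer)\n")
  cat(sprintf("  cycles: %d; mean growth rate %.4g/min\n",
              object@nCycles, object@growthRate))
  cat(sprintf("  D(Age Model)  = %6.2f%%\n", object@dAge@pct))
  cat(sprintf("  D(Size Model) = %6.2f%%\n", object@dSize@pct))
  cat(sprintf("  corr(division age, birth size) = %.3f (perm. p = %.3g)\n",
              object@correlation, object@correlationP))
  cat(sprintf("  preferred model: %s\n", object@preferred))
})

#' Robustness of the stable size distribution to noise
#'
#' Scans a noise level and reports the distance between the noiseless stable
#' size distribution and the one obtained at each level. For
#' `"growth_rate"` and `"septum"` the corresponding extended Size Model is
#' solved per CV ([solveGrowthVariability()], [solveSeptumNoise()]). For
#' `"division_time_measurement"` the scan is stochastic: sizer lineages are
#' simulated, the measurement layer applied at each CV, the division rate
#' re-estimated and the Size Model re-solved, comparing against the
#' noiseless pipeline output.
#'
#' @param B a size-indexed [DivisionRate].
#' @param growth a [GrowthLaw].
#' @param noiseType `"growth_rate"`, `"septum"` or
#'   `"division_time_measurement"`.
#' @param cvList nonnegative, sorted CVs (fractions).
#' @param config [SimConfig] for the stochastic scan (default: sparse-tree
#'   sizer lineages under `B` and `growth`).
#' @param nCycles cycles per stochastic evaluation.
#' @param tol,maxIter solver controls.
#' @return `data.frame` with columns `cv`, `distance_pct`.
#' @export
robustnessScan <- function(B, growth,
                           noiseType = c("growth_rate", "septum",
                                         "division_time_measurement"),
                           cvList = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                           config = NULL, nCycles = 5000L,
                           tol = 1e-8, maxIter = 60000L) {
  noiseType <- match.arg(noiseType)
  if (any(cvList < 0) || is.unsorted(cvList))
    stopf("cvList must be nonnegative and sorted")
  if (noiseType %in% c("growth_rate", "septum")) {
    solveOne <- function(cv) {
      if (noiseType == "growth_rate")
        solveGrowthVariability(B, growth, cv = cv, tol = tol, maxIter = maxIter)
      else
        solveSeptumNoise(B, growth, cv = cv, tol = tol, maxIter = maxIter)
    }
    base <- sizeMarginal(solveOne(0))
    ds <- vapply(cvList, function(cv) {
      distancePct(densityDistance(base, sizeMarginal(solveOne(cv))))
    }, 1)
    return(data.frame(cv = cvList, distance_pct = ds))
  }
  ## stochastic: measurement noise on the division time
  if (is.null(config))
    config <- simConfig("sizer", divisionRate = B, growthLaw = growth,
                        meanRate = growth@rate, topology = "sparse_tree",
                        generations = as.integer(ceiling(nCycles / 100) + 10L),
                        nChannels = 100L, acquisitionDt = 1)
  xMax <- max(rateGrid(B))
  grid <- cellCenters(xMax, 2L^7L)
  tracks0 <- simulateMotherMachine(config)
  pipeline <- function(tr) {
    cyc <- extractCycles(tr, generationWindow = c(10L, config@generations))
    Bhat <- estimateSizeRate(cyc, growth, grid = grid)
    sizeMarginal(solveStable("size", Bhat, growth, xMax = xMax,
                             topology = config@topology, tol = tol,
                             maxIter = maxIter))
  }
  base <- pipeline(tracks0)
  ds <- vapply(cvList, function(cv) {
    cfg <- config
    cfg@divisionTimeNoiseCV <- cv
    tr <- if (cv > 0) applyMeasurementLayer(tracks0, cfg) else tracks0
    distancePct(densityDistance(base, pipeline(tr)))
  }, 1)
  data.frame(cv = cvList, distance_pct = ds)
}
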