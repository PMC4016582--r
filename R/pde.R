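#' @include division-rate.R growth-law.R density-grid.R
NULL

## ---------------------------------------------------------------------------
## Upwind finite-volume solvers for the structured-population equations.
##
## All solvers share the same scheme ingredients, chosen so that the discrete
## dynamics inherit the conservation structure of the continuous models:
##  * transport: first-order upwind, flux F_{k+1/2} = v(x_k) n_k evaluated
##    entirely at the upwind cell, so that for v(x) = v x the discrete
##    biomass grows at exactly rate v;
##  * division loss: integrated exactly over a step (multiplication by
##    exp(-B dt)), removing the O(B^2 dt) eigenvalue bias of explicit Euler;
##  * division gain: conservative deposition — the cells lost to division in
##    a size cell re-enter as daughters at half (or theta times) the mother
##    size, split onto the two neighbouring grid cells with linear weights,
##    which conserves cell number and biomass to rounding;
##  * renormalization each step; the Malthus coefficient is log(growth
##    factor)/dt averaged over the final iterations.
## Full genealogical trees keep both daughters (2 per division); sparse
## (mother-machine) trees keep one, which is the "4 -> 2" renewal-factor
## modification, and their Malthus coefficient is ~0.
## ---------------------------------------------------------------------------

## Linear deposition weights for target positions p (um) on the cell-centered
## grid with spacing dx: returns K x length(p) sparse info as two rows of
## indices + weights; weights falling below the grid are clamped into cell 1.
depositWeights <- function(p, dx, K) {
  s <- p / dx + 0.5  # fractional cell index (1-based centers)
  iLo <- floor(s)
  wHi <- s - iLo
  wLo <- 1 - wHi
  iHi <- iLo + 1L
  ## mass below the grid is folded into the first cell
  wLo[iLo < 1L] <- 0; iLo[iLo < 1L] <- 1L
  wHi[iHi < 1L] <- 0; iHi[iHi < 1L] <- 1L
  ## mass beyond X_max is dropped (boundary leakage, logged)
  wLo[iLo > K] <- 0; iLo[iLo > K] <- K
  wHi[iHi > K] <- 0; iHi[iHi > K] <- K
  list(iLo = as.integer(iLo), wLo = wLo, iHi = as.integer(iHi), wHi = wHi)
}

## Dense K x K deposition matrix: column m = where daughters of a divider in
## size cell m land. `thetas`/`thetaW`: septum fractions and their weights
## (both daughters theta and 1-theta are deposited; `perDivision` scales the
## number of daughters kept: 2 full tree, 1 sparse tree).
divisionKernel <- function(xc, dx, thetas, thetaW, perDivision) {
  K <- length(xc)
  W <- matrix(0, K, K)
  for (i in seq_along(thetas)) {
    for (th in unique(c(thetas[i], 1 - thetas[i]))) {
      mult <- if (abs(thetas[i] - 0.5) < 1e-12) 2 else 1
      dw <- depositWeights(th * xc, dx, K)
      for (m in seq_len(K)) {
        W[dw$iLo[m], m] <- W[dw$iLo[m], m] + mult * thetaW[i] * dw$wLo[m]
        W[dw$iHi[m], m] <- W[dw$iHi[m], m] + mult * thetaW[i] * dw$wHi[m]
      }
    }
  }
  W * (perDivision / 2)
}

noConvergence <- function(iter, residual, tol) {
  stop(errorCondition(
    sprintf("no stable distribution reached: residual %.3g > tol %.3g after %d iterations",
            residual, tol, iter),
    class = c("sizecontrol_no_convergence", "error", "condition")))
}

#' Solve a structured-population model for its stable distribution
#'
#' Renormalized forward iteration of the growth-fragmentation equations with
#' a first-order upwind finite-volume scheme on 2^7-point cell-centered
#' grids, run until the renormalized density changes by less than `tol`
#' between steps. Returns the stable distribution N and the Malthus
#' coefficient lambda such that \eqn{n(t) \approx e^{\lambda t} N}.
#'
#' * `model = "size"`: the one-dimensional size-structured equation
#'   \eqn{\partial_t n + \partial_x(v(x) n) = -B_s n + 4 B_s(2x) n(2x)}.
#' * `model = "age"` / `"age_size"`: the two-dimensional age-and-size
#'   equation with renewal boundary \eqn{n(t, 0, x) = 4\int B(a, 2x)
#'   n(t, a, 2x)\,da}; an age-indexed `B` gives the Age Model (timer), a
#'   size-indexed `B` the Size Model restriction.
#' * `topology = "sparse_tree"` keeps one daughter per division (renewal
#'   factors 4 -> 2, and 2 -> 1 for the age marginal); lambda is then ~0.
#'
#' The time step satisfies the CFL stability bound
#' `dt = safety / (max v * nSize/xMax + nAge/aMax)` (the age term only for
#' the two-dimensional models).
#'
#' @param model `"age"`, `"size"` or `"age_size"`.
#' @param B a [DivisionRate] (index `"age"` or `"size"`; `model = "size"`
#'   requires a size-indexed rate).
#' @param growth a [GrowthLaw].
#' @param aMax,xMax domain bounds (min, um); defaults: the rate grid bound
#'   for its own index, `3 log(2)/rate` for the age bound, 10 um otherwise.
#' @param nAge,nSize grid sizes (default 2^7).
#' @param topology `"full_tree"` or `"sparse_tree"`.
#' @param safety CFL safety factor.
#' @param tol sup-norm convergence tolerance on the renormalized density.
#' @param maxIter iteration cap; non-convergence is an error (expected, by
#'   theory, for timer control with uncapped exponential growth).
#' @param init optional positive initial density (matrix `nAge x nSize` or
#'   vector `nSize`).
#' @param lambdaWindow number of final steps over which lambda is averaged.
#' @return a [StableDistribution].
#' @examples
#' ## constant age hazard b: lambda = b and N(a) = 2b exp(-2ba)
#' Ba <- divisionRate("age", seq(0, 150, length.out = 64), rep(0.0347, 64))
#' \donttest{
#' sol <- solveStable("age", Ba, growthLaw(0.0274), xMax = 10)
#' malthusCoefficient(sol)
#' }
#' @export
solveStable <- function(model = c("age_size", "age", "size"), B, growth,
                        aMax = NULL, xMax = NULL, nAge = 2L^7L, nSize = 2L^7L,
                        topology = c("full_tree", "sparse_tree"),
                        safety = 0.9, tol = 1e-8, maxIter = 60000L,
                        init = NULL, lambdaWindow = 100L) {
  model <- match.arg(model)
  topology <- match.arg(topology)
  d <- if (topology == "full_tree") 2 else 1
  if (is.null(xMax)) xMax <- if (rateIndex(B) == "size") max(rateGrid(B)) else 10
  if (is.null(aMax)) aMax <- if (rateIndex(B) == "age") max(rateGrid(B)) else
    3 * log(2) / growth@rate
  if (model == "size") {
    if (rateIndex(B) != "size") stopf("model 'size' needs a size-indexed rate")
    return(solveSizeKernel(B, growth, xMax, nSize, d, safety, tol, maxIter,
                           init, lambdaWindow, thetas = 0.5, thetaW = 1))
  }
  solveAgeSize(B, growth, aMax, xMax, nAge, nSize, d, safety, tol, maxIter,
               init, lambdaWindow)
}

## Shared 1-D size-structured engine; thetas/thetaW discretize the septum
## kernel (a point mass at 1/2 for the plain Size Model).
solveSizeKernel <- function(B, growth, xMax, K, d, safety, tol, maxIter,
                            init, lambdaWindow, thetas, thetaW) {
  dx <- xMax / K
  xc <- cellCenters(xMax, K)
  v <- pmax(growthRateAt(growth, xc), 0)
  Bv <- divisionRateAt(B, xc)
  if (any(!is.finite(Bv))) stopf("division rate not finite on the grid")
  dt <- safety / (max(v) * K / xMax)
  if (!is.finite(dt) || dt <= 0) stopf("degenerate CFL time step")
  Dfac <- exp(-dt * Bv)
  W <- divisionKernel(xc, dx, thetas, thetaW, d)
  n <- if (is.null(init)) exp(-((xc - xMax / 3)^2) / (2 * (xMax / 6)^2)) else
    as.numeric(init)
  if (length(n) != K || any(n < 0) || sum(n) == 0)
    stopf("init must be a positive vector of length nSize")
  n <- n / (sum(n) * dx)
  lamBuf <- numeric(lambdaWindow)
  resid <- Inf
  lamPrev <- 0
  for (it in seq_len(maxIter)) {
    Fup <- v * n
    n1 <- n + (dt / dx) * (c(0, Fup[-K]) - Fup)
    div <- n1 * (1 - Dfac)
    ## births carry half a step of cohort growth (they arrive mid-step on
    ## average), cancelling the O(lambda^2 dt) splitting bias
    n1 <- n1 * Dfac + exp(lamPrev * dt / 2) * as.numeric(W %*% div)
    g <- sum(n1) * dx
    lamPrev <- log(g) / dt
    lamBuf[(it - 1L) %% lambdaWindow + 1L] <- log(g) / dt
    n1 <- n1 / g
    resid <- max(abs(n1 - n))
    n <- n1
    if (resid < tol && it > lambdaWindow) {
      leak <- dt * v[K] * n[K] * 1  # per-step boundary outflow fraction
      return(packSolution(list(size = xc), n, mean(lamBuf), resid, it, leak))
    }
  }
  noConvergence(maxIter, resid, tol)
}

solveAgeSize <- function(B, growth, aMax, xMax, M, K, d, safety, tol, maxIter,
                         init, lambdaWindow) {
  da <- aMax / M; dx <- xMax / K
  ac <- cellCenters(aMax, M)
  xc <- cellCenters(xMax, K)
  v <- pmax(growthRateAt(growth, xc), 0)
  Bmat <- if (rateIndex(B) == "age")
    matrix(divisionRateAt(B, ac), M, K) else
    matrix(divisionRateAt(B, xc), M, K, byrow = TRUE)
  dt <- safety / (max(v) * K / xMax + M / aMax)
  Dfac <- exp(-dt * Bmat)
  Vmat <- matrix(v, M, K, byrow = TRUE)
  W <- divisionKernel(xc, dx, thetas = 0.5, thetaW = 1, perDivision = d)
  nuA <- dt / da
  n <- if (is.null(init))
    outer(exp(-3 * ac / aMax), exp(-((xc - xMax / 3)^2) / (2 * (xMax / 6)^2)))
  else as.matrix(init)
  if (!all(dim(n) == c(M, K)) || any(n < 0) || sum(n) == 0)
    stopf("init must be a positive nAge x nSize matrix")
  n <- n / (sum(n) * da * dx)
  lamBuf <- numeric(lambdaWindow)
  resid <- Inf
  lamPrev <- 0
  zeroRow <- rep(0, K)
  for (it in seq_len(maxIter)) {
    Fup <- Vmat * n
    n1 <- n + nuA * (rbind(zeroRow, n[-M, , drop = FALSE]) - n) +
      (dt / dx) * (cbind(0, Fup[, -K, drop = FALSE]) - Fup)
    div <- n1 * (1 - Dfac)
    n1 <- n1 * Dfac
    colDiv <- .colSums(div, M, K)  # divisions per size cell (density sum)
    n1[1L, ] <- n1[1L, ] + exp(lamPrev * dt / 2) * as.numeric(W %*% colDiv)
    g <- sum(n1) * da * dx
    lamPrev <- log(g) / dt
    lamBuf[(it - 1L) %% lambdaWindow + 1L] <- log(g) / dt
    n1 <- n1 / g
    resid <- max(abs(n1 - n))
    n <- n1
    if (resid < tol && it > lambdaWindow) {
      leak <- dt * (sum(v[K] * n[, K]) * da + sum(n[M, ]) * dx)
      return(packSolution(list(age = ac, size = xc), n, mean(lamBuf),
                          resid, it, leak))
    }
  }
  noConvergence(maxIter, resid, tol)
}

packSolution <- function(axes, values, lambda, resid, iter, leak) {
  vals <- if (is.matrix(values)) values else array(values, dim = length(values))
  tot <- gridIntegralRaw(axes, vals)
  dens <- new("DensityGrid", axes = axes, values = vals / tot, normalized = TRUE)
  sizeM <- marginalDensity(dens, "size")
  sizeM <- densityGrid(densityValues(sizeM), size = gridAxis(sizeM, "size"))
  ageM <- NULL
  if ("age" %in% names(axes)) {
    ageM <- marginalDensity(dens, "age")
    ageM <- densityGrid(densityValues(ageM), age = gridAxis(ageM, "age"))
  }
  new("StableDistribution", density = dens, malthus = lambda,
      ageMarginal = ageM, sizeMarginal = sizeM, residual = resid,
      iterations = as.integer(iter), converged = TRUE, leakage = leak)
}

#' @rdname malthusCoefficient
setMethod("malthusCoefficient", "StableDistribution", function(x) x@malthus)

#' @rdname malthusCoefficient
setMethod("sizeMarginal", "StableDistribution", function(x) x@sizeMarginal)

#' @rdname malthusCoefficient
setMethod("ageMarginal", "StableDistribution", function(x) x@ageMarginal)

#' @rdname densityValues
setMethod("densityValues", "StableDistribution", function(x) densityValues(x@density))

#' @rdname densityValues
setMethod("gridAxis", "StableDistribution", function(x, axis) gridAxis(x@density, axis))

setMethod("show", "StableDistribution", function(object) {
  cat(sprintf(
    "StableDistribution: lambda = %.5g/min, %d iterations, residual %.2e\n",
    object@malthus, object@iterations, object@residual))
  show(object@density)
})

#' Size Model with individual growth-rate variability
#'
#' Solves the size- and growth-rate-structured extension of the Size Model:
#' each cell carries an individual exponential rate v'; transport acts per
#' rate slice and newborn cells draw their rate independently from the
#' population rate distribution rho (i.i.d. inheritance). The rate axis uses
#' 100 equally spaced points on `[0.9 v_min, 1.1 v_max]`.
#'
#' @param B a size-indexed [DivisionRate].
#' @param growth a [GrowthLaw] (evaluated at the core rate; slices scale it).
#' @param cv coefficient of variation of the truncated-Gaussian rate
#'   distribution (around `growth@rate`, truncated at 3 sigma); `cv = 0`
#'   reduces exactly to the plain Size Model.
#' @param rates,rateWeights explicit discrete rate distribution
#'   (overrides `cv`).
#' @param nRates rate-axis resolution.
#' @inheritParams solveStable
#' @return a [StableDistribution] whose density has axes `size`, `rate`;
#'   `sizeMarginal(x)` is the quantity compared across noise levels.
#' @export
solveGrowthVariability <- function(B, growth, cv = NULL, rates = NULL,
                                   rateWeights = NULL, nRates = 100L,
                                   xMax = NULL, nSize = 2L^7L,
                                   topology = c("full_tree", "sparse_tree"),
                                   safety = 0.9, tol = 1e-8, maxIter = 60000L,
                                   lambdaWindow = 100L) {
  topology <- match.arg(topology)
  d <- if (topology == "full_tree") 2 else 1
  vbar <- growth@rate
  if (is.null(rates)) {
    if (is.null(cv)) stopf("give either cv or an explicit rate distribution")
    if (cv < 0) stopf("cv must be nonnegative")
    if (cv == 0) { rates <- vbar; rateWeights <- 1 } else {
      vLo <- max(vbar * (1 - 3 * cv), 0.05 * vbar)
      vHi <- vbar * (1 + 3 * cv)
      rates <- seq(0.9 * vLo, 1.1 * vHi, length.out = nRates)
      rateWeights <- dnorm(rates, vbar, cv * vbar)
      rateWeights[rates < vLo | rates > vHi] <- 0
    }
  }
  rateWeights <- rateWeights / sum(rateWeights)
  R <- length(rates)
  if (is.null(xMax)) xMax <- max(rateGrid(B))
  K <- nSize
  dx <- xMax / K
  xc <- cellCenters(xMax, K)
  vx <- pmax(growthRateAt(growth, xc), 0)
  Vmat <- outer(vx, rates / vbar)  # K x R speeds
  Bv <- divisionRateAt(B, xc)
  dt <- safety / (max(Vmat) * K / xMax)
  Dfac <- exp(-dt * Bv)
  W <- divisionKernel(xc, dx, thetas = 0.5, thetaW = 1, perDivision = d)
  n <- outer(exp(-((xc - xMax / 3)^2) / (2 * (xMax / 6)^2)), rateWeights)
  if (R == 1L) n <- matrix(n, K, 1L)
  n <- n / (sum(n) * dx)
  lamBuf <- numeric(lambdaWindow)
  resid <- Inf
  lamPrev <- 0
  for (it in seq_len(maxIter)) {
    Fup <- Vmat * n
    n1 <- n + (dt / dx) * (rbind(0, Fup[-K, , drop = FALSE]) - Fup)
    div <- n1 * (1 - Dfac)
    n1 <- n1 * Dfac
    colDiv <- .rowSums(div, K, R)  # divisions per size cell, summed over rates
    births <- exp(lamPrev * dt / 2) * as.numeric(W %*% colDiv)
    n1 <- n1 + outer(births, rateWeights)
    g <- sum(n1) * dx
    lamPrev <- log(g) / dt
    lamBuf[(it - 1L) %% lambdaWindow + 1L] <- log(g) / dt
    n1 <- n1 / g
    resid <- max(abs(n1 - n))
    n <- n1
    if (resid < tol && it > lambdaWindow) {
      leak <- dt * sum(Vmat[K, ] * n[K, ])
      if (R == 1L)  # degenerate rate axis: plain Size Model
        return(packSolution(list(size = xc), as.numeric(n), mean(lamBuf),
                            resid, it, leak))
      return(packSolution(list(size = xc, rate = rates), n, mean(lamBuf),
                          resid, it, leak))
    }
  }
  noConvergence(maxIter, resid, tol)
}

#' Size Model with noisy septum positioning
#'
#' Solves the Size Model with a septum-position kernel q on (0, 1): a mother
#' of size y produces daughters of sizes theta*y and (1-theta)*y with theta
#' drawn from q (symmetric about 1/2). The division gain becomes
#' \eqn{2\int B(y) q(x/y) n(y)/y\, dy}, which reduces to the classical
#' \eqn{4B(2x)n(2x)} when q is a point mass at 1/2 — and `cv = 0` reproduces
#' the plain Size Model exactly.
#'
#' @param B a size-indexed [DivisionRate].
#' @param growth a [GrowthLaw].
#' @param cv coefficient of variation of the truncated-Gaussian septum
#'   kernel around 1/2 (support (0.2, 0.8)).
#' @param thetas,thetaW explicit kernel discretization (overrides `cv`);
#'   must be symmetric about 1/2 (asymmetry warns) and stay clear of 0 and 1
#'   (mass outside (0.05, 0.95) errors).
#' @param nTheta kernel discretization points.
#' @inheritParams solveStable
#' @return a [StableDistribution] (size axis only).
#' @export
solveSeptumNoise <- function(B, growth, cv = NULL, thetas = NULL,
                             thetaW = NULL, nTheta = 101L, xMax = NULL,
                             nSize = 2L^7L,
                             topology = c("full_tree", "sparse_tree"),
                             safety = 0.9, tol = 1e-8, maxIter = 60000L,
                             lambdaWindow = 100L) {
  topology <- match.arg(topology)
  d <- if (topology == "full_tree") 2 else 1
  if (is.null(thetas)) {
    if (is.null(cv)) stopf("give either cv or an explicit septum kernel")
    if (cv < 0) stopf("cv must be nonnegative")
    if (cv == 0) { thetas <- 0.5; thetaW <- 1 } else {
      sdTh <- 0.5 * cv
      thetas <- seq(max(0.2, 0.5 - 4 * sdTh), min(0.8, 0.5 + 4 * sdTh),
                    length.out = nTheta)
      thetaW <- dnorm(thetas, 0.5, sdTh)
    }
  }
  thetaW <- thetaW / sum(thetaW)
  if (any(thetas <= 0.05 | thetas >= 0.95))
    stopf("septum kernel has mass near 0/1: degenerate daughters")
  m1 <- sum(thetas * thetaW)
  if (abs(m1 - 0.5) > 1e-6)
    warnf("septum kernel is asymmetric (mean %.4g); daughters use theta and 1-theta", m1)
  if (is.null(xMax)) xMax <- max(rateGrid(B))
  solveSizeKernel(B, growth, xMax, nSize, d, safety, tol, maxIter,
                  init = NULL, lambdaWindow, thetas = thetas, thetaW = thetaW)
}
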