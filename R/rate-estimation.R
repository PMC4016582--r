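#' @include kde.R division-rate.R
NULL

#' Estimate the age-indexed division rate from cycle data
#'
#' Survival-hazard estimator: the density f of division ages is estimated by
#' kernel smoothing ([kde1d()]) and the hazard is \eqn{B_a(a) =
#' f(a) / S(a)} with \eqn{S(a) = 1 - \int_0^a f} the survival function.
#' Where the survival mass drops below `sMin` the ratio is no longer
#' identifiable from data; the hazard is continued at its last reliable
#' value (constant continuation) and the reliable-support mask records the
#' switch. Incomplete (right-censored) cycles are excluded; a note is
#' emitted when they exceed 10% of the data.
#'
#' @param cycles cycle `data.frame` ([extractCycles()] / [simulateCycles()]).
#' @param grid age grid (min); default 2^7 cell-centered nodes on
#'   `[0, max division age]`.
#' @param sMin survival threshold below which the hazard is extrapolated.
#' @param bw kernel bandwidth (default Silverman).
#' @param minCycles minimum complete cycles (warning below, error at 0).
#' @return a [DivisionRate] with `index = "age"`.
#' @export
estimateAgeRate <- function(cycles, grid = NULL, sMin = 0.02, bw = NULL,
                            minCycles = 100L) {
  ages <- completeColumn(cycles, "division_age_min", minCycles)
  if (is.null(grid)) grid <- cellCenters(max(ages), 2L^7L)
  f <- kde1d(ages, grid = grid, bw = bw, axis = "age")
  fv <- densityValues(f)
  S <- pmax(1 - cumtrapz(grid, fv), 0)
  reliable <- S >= sMin
  B <- numeric(length(grid))
  B[reliable] <- fv[reliable] / S[reliable]
  if (any(!reliable)) {
    lastB <- if (any(reliable)) B[max(which(reliable))] else 0
    B[!reliable] <- lastB
  }
  divisionRate("age", grid, pmax(B, 0), reliable = reliable,
               extrapolation = "constant")
}

#' Estimate the size-indexed division rate from cycle data
#'
#' Size-coordinate hazard estimator: with growth speed v(x), the density
#' \eqn{\psi} of division sizes satisfies \eqn{\psi(x) = \pi(x) B_s(x)/v(x)}
#' where \eqn{\pi(x)} is the at-risk fraction — the probability that a cycle
#' passes through size x undivided (birth size <= x < division size). Hence
#' \eqn{B_s(x) = v(x)\,\psi(x)/\pi(x)}. \eqn{\psi} is kernel-smoothed
#' ([kde1d()]) and \eqn{\pi} evaluated exactly from the empirical birth- and
#' division-size distributions. The rate is zero below the smallest birth
#' size, and continued at its last reliable value where \eqn{\pi < pMin}.
#'
#' @param cycles cycle `data.frame`.
#' @param growthLaw a [GrowthLaw], strictly positive on the observed size
#'   range.
#' @param grid size grid (um); default 2^7 cell-centered nodes on
#'   `[0, max division size]`.
#' @param pMin at-risk threshold below which the hazard is extrapolated.
#' @param bw kernel bandwidth (default Silverman).
#' @param minCycles minimum complete cycles.
#' @return a [DivisionRate] with `index = "size"`.
#' @export
estimateSizeRate <- function(cycles, growthLaw, grid = NULL, pMin = 0.02,
                             bw = NULL, minCycles = 100L) {
  xd <- completeColumn(cycles, "division_size_um", minCycles)
  xb <- completeColumn(cycles, "birth_size_um", 0L)
  if (is.null(grid)) grid <- cellCenters(max(xd), 2L^7L)
  v <- growthRateAt(growthLaw, grid)
  obs <- grid >= min(xb) & grid <= max(xd)
  if (all(v[obs] <= 0))
    stopf("growth law is zero on the observed size range")
  psi <- densityValues(kde1d(xd, grid = grid, bw = bw, axis = "size"))
  Fb <- stats::ecdf(xb); Fd <- stats::ecdf(xd)
  piAtRisk <- pmax(Fb(grid) - Fd(grid), 0)
  reliable <- piAtRisk >= pMin & v > 0
  B <- numeric(length(grid))
  B[reliable] <- v[reliable] * psi[reliable] / piAtRisk[reliable]
  belowBirth <- grid < min(xb)
  aboveIdx <- if (any(reliable)) grid > grid[max(which(reliable))] else rep(TRUE, length(grid))
  lastB <- if (any(reliable)) B[max(which(reliable))] else 0
  B[!reliable & aboveIdx] <- lastB
  B[belowBirth] <- 0
  divisionRate("size", grid, pmax(B, 0), reliable = reliable,
               extrapolation = "constant")
}

completeColumn <- function(cycles, col, minCycles) {
  cc <- cycles[cycles$complete, , drop = FALSE]
  if (nrow(cc) == 0L) stopf("no complete cycles")
  fracCensored <- 1 - nrow(cc) / nrow(cycles)
  if (fracCensored > 0.10)
    message(sprintf("note: %.1f%% of cycles are incomplete and excluded (censoring bias possible)",
                    100 * fracCensored))
  x <- cc[[col]]
  x <- x[is.finite(x)]
  if (minCycles > 0L && length(x) < minCycles)
    warnf("only %d complete cycles (< %d): estimate will have a narrow reliable support",
          length(x), minCycles)
  if (length(x) < 2L) stopf("no usable cycles for %s", col)
  x
}
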