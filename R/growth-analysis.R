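#' @include cycles.R kde.R
NULL

#' Linear and exponential fits of single-cell length versus time
#'
#' Fits both growth models to one cell's length time series: a linear fit by
#' ordinary least squares and an exponential fit by least squares on
#' log-length (the slope is the elongation rate). Both coefficients of
#' determination are computed on the original length scale, so the two
#' models are directly comparable.
#'
#' @param time observation times (min), >= 3 distinct values.
#' @param length lengths (um), positive.
#' @param cellId optional identifier copied into the result.
#' @return one-row `data.frame`: `cell_id, rate_per_min, initial_length_um,
#'   r2_linear, r2_exponential`.
#' @export
fitSingleCellGrowth <- function(time, length, cellId = NA) {
  if (length(time) < 3L || length(unique(time)) < 3L)
    stopf("need at least 3 distinct time points")
  if (any(!is.finite(length)) || any(length <= 0))
    stopf("lengths must be positive")
  t0 <- time - time[1L]
  linFit <- lm(length ~ t0)
  expFit <- lm(log(length) ~ t0)
  ssTot <- sum((length - mean(length))^2)
  r2 <- function(pred) 1 - sum((length - pred)^2) / ssTot
  data.frame(cell_id = cellId,
             rate_per_min = unname(coef(expFit)[2L]),
             initial_length_um = exp(unname(coef(expFit)[1L])),
             r2_linear = r2(fitted(linFit)),
             r2_exponential = r2(exp(fitted(expFit))))
}

#' Binned length-increment curve and exponential-range detection
#'
#' For every pair of consecutive frames within a cell, records (length,
#' length increase over one acquisition step), bins by length, and reports
#' the mean increment with its standard error per bin. Under exponential
#' growth the mean increment is proportional to length
#' (\eqn{\ell (e^{v\Delta t} - 1)}), so a weighted proportional fit over the
#' central size range provides the reference line; the thresholds
#' `x_min`/`x_max` are set where, searching outward from the fit range, the
#' binned mean first departs from that line by more than `semMultiple`
#' standard errors — the sizes beyond which growth can no longer be assumed
#' exponential.
#'
#' @param tracks a TrackTable `data.frame` (increments are taken within
#'   cells only, never across a division).
#' @param binWidth bin width (um).
#' @param fitRange length range (um) for the reference fit; default the
#'   central quartile range of observed lengths.
#' @param minCount minimum occupancy for a bin to carry an estimate.
#' @param semMultiple departure threshold in SEM units.
#' @param relTol relative-departure floor: a bin is flagged only if it also
#'   deviates from the proportional line by more than this fraction of the
#'   predicted increment (the SEM shrinks as n^-1/2, so without a floor any
#'   minute quadrature wiggle is eventually "significant").
#' @return an object of class `IncrementCurve`: list with `bins` (a
#'   `data.frame` `bin_center_um, mean_increment_um, sem_um, count`),
#'   `slope`, `intercept` (free linear fit on the fit range), `propSlope`
#'   (proportional fit), `xMin`, `xMax`, `fitRange`, `dt`.
#' @export
incrementCurve <- function(tracks, binWidth = 0.2, fitRange = NULL,
                           minCount = 50L, semMultiple = 2, relTol = 0.01) {
  if (binWidth <= 0) stopf("binWidth must be positive")
  dt <- as.data.table(tracks)
  requireCols(dt, c("cell_id", "time_min", "length_um"), "tracks")
  setorder(dt, cell_id, time_min)
  inc <- dt[, .(len = length_um[-.N], d = diff(length_um)), by = cell_id]
  if (nrow(inc) < 1L) stopf("no consecutive observation pairs")
  step <- stats::median(dt[, diff(time_min), by = cell_id]$V1)
  if (is.null(fitRange)) fitRange <- unname(quantile(inc$len, c(0.25, 0.75)))
  b0 <- floor(min(inc$len) / binWidth) * binWidth
  inc[, bin := b0 + (floor((len - b0) / binWidth) + 0.5) * binWidth]
  bins <- inc[, .(mean_increment_um = mean(d),
                  sem_um = sd(d) / sqrt(.N), count = .N), by = bin]
  setorder(bins, bin)
  data.table::setnames(bins, "bin", "bin_center_um")
  ok <- bins$count >= minCount & is.finite(bins$sem_um) & bins$sem_um > 0
  inFit <- ok & bins$bin_center_um >= fitRange[1L] & bins$bin_center_um <= fitRange[2L]
  if (!any(inFit))
    stopf("no populated bins in the fit range [%.3g, %.3g]", fitRange[1L], fitRange[2L])
  w <- 1 / bins$sem_um[inFit]^2
  x <- bins$bin_center_um[inFit]; y <- bins$mean_increment_um[inFit]
  propSlope <- sum(w * x * y) / sum(w * x^2)
  X <- cbind(1, x)
  beta <- solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), y * sqrt(w)))
  detect <- function(dir) {
    centers <- bins$bin_center_um
    cand <- if (dir > 0) which(ok & centers > fitRange[2L])
            else rev(which(ok & centers < fitRange[1L]))
    edge <- if (dir > 0) fitRange[2L] else fitRange[1L]
    lastGood <- edge
    for (i in cand) {
      pred <- propSlope * centers[i]
      dev <- abs(bins$mean_increment_um[i] - pred)
      if (dev > semMultiple * bins$sem_um[i] && dev > relTol * abs(pred))
        return((lastGood + centers[i]) / 2)
      lastGood <- centers[i]
    }
    lastGood
  }
  out <- list(bins = setDF(bins[, .(bin_center_um, mean_increment_um, sem_um, count)]),
              slope = beta[2L], intercept = beta[1L], propSlope = propSlope,
              xMin = detect(-1L), xMax = detect(+1L),
              fitRange = fitRange, dt = step)
  class(out) <- "IncrementCurve"
  out
}

#' @export
print.IncrementCurve <- function(x, ...) {
  cat(sprintf("IncrementCurve: %d bins, dt = %.3g min\n", nrow(x$bins), x$dt))
  cat(sprintf("  proportional slope %.4g um/um (implied rate %.4g/min)\n",
              x$propSlope, log(1 + x$propSlope) / x$dt))
  cat(sprintf("  exponential range [%.3g, %.3g] um\n", x$xMin, x$xMax))
  invisible(x)
}

#' Empirical growth-rate and septum-ratio distributions
#'
#' Kernel-smoothed distributions of the fitted single-cell elongation rates
#' and of the septum ratios, with their coefficients of variation and a
#' Shapiro-Wilk normality statistic (reported, not thresholded).
#'
#' @param cycles a cycle `data.frame` from [extractCycles()] or
#'   [simulateCycles()].
#' @param minCycles minimum number of complete cycles required.
#' @return an object of class `NoiseSummary`: list with `rateDensity`,
#'   `rateMean`, `rateCV`, `rateShapiroW`, `septumDensity`, `septumCV`,
#'   `septumShapiroW`, `n`.
#' @export
noiseSummary <- function(cycles, minCycles = 30L) {
  cc <- cycles[cycles$complete & is.finite(cycles$growth_rate_per_min), ]
  if (nrow(cc) < minCycles)
    stopf("too few cycles: %d complete (need >= %d)", nrow(cc), minCycles)
  v <- cc$growth_rate_per_min
  th <- cycles$septum_ratio[is.finite(cycles$septum_ratio)]
  shapiroW <- function(x) {
    if (length(unique(x)) < 3L) return(NA_real_)
    if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
    unname(shapiro.test(x)$statistic)
  }
  kdeOrNull <- function(x, axis) {
    if (length(x) < 2L || var(x) == 0) return(NULL)
    kde1d(x, grid = seq(min(x) - 3 * bw.nrd0(x), max(x) + 3 * bw.nrd0(x),
                        length.out = 2L^7L), axis = axis)
  }
  out <- list(rateDensity = kdeOrNull(v, "rate"),
              rateMean = mean(v), rateCV = sd(v) / mean(v),
              rateShapiroW = shapiroW(v),
              septumDensity = kdeOrNull(th, "septum"),
              septumCV = if (length(th) >= 2L) sd(th) / mean(th) else NA_real_,
              septumShapiroW = shapiroW(th),
              n = nrow(cc))
  class(out) <- "NoiseSummary"
  out
}

#' @export
print.NoiseSummary <- function(x, ...) {
  cat(sprintf("NoiseSummary (%d cycles)\n", x$n))
  cat(sprintf("  growth rate: mean %.4g/min, CV %.3g (Shapiro W %.3g)\n",
              x$rateMean, x$rateCV, x$rateShapiroW))
  cat(sprintf("  septum ratio: CV %.3g (Shapiro W %.3g)\n",
              x$septumCV, x$septumShapiroW))
  invisible(x)
}
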