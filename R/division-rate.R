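#' @include AllGenerics.R
NULL

#' Construct a tabulated division rate
#'
#' @param index `"age"` or `"size"`.
#' @param grid strictly increasing nonnegative grid (min or um).
#' @param values nonnegative hazards (1/min) at the grid nodes.
#' @param reliable logical support mask (defaults to all `TRUE`).
#' @param extrapolation `"constant"` (continue at the edge values) or
#'   `"zero"` beyond/below the grid.
#' @return a [DivisionRate].
#' @examples
#' ## steep sizer: negligible hazard below ~3 um, steeply increasing above
#' xs <- seq(0, 8, length.out = 200)
#' divisionRate("size", xs, 0.02 * (xs / 3)^8)
#' @export
divisionRate <- function(index, grid, values, reliable = NULL,
                         extrapolation = "constant") {
  if (is.null(reliable)) reliable <- rep(TRUE, length(grid))
  new("DivisionRate", index = index, grid = as.numeric(grid),
      values = as.numeric(values), reliable = reliable,
      extrapolation = extrapolation)
}

#' Tabulate a hazard function onto a grid
#'
#' @param fun vectorized hazard function (1/min).
#' @param index `"age"` or `"size"`.
#' @param upper grid upper bound (min or um).
#' @param n number of grid nodes.
#' @param ... passed to [divisionRate()].
#' @return a [DivisionRate].
#' @export
tabulateDivisionRate <- function(fun, index, upper, n = 512L, ...) {
  grid <- seq(0, upper, length.out = n)
  divisionRate(index, grid, pmax(fun(grid), 0), ...)
}

#' @rdname divisionRateAt
setMethod("divisionRateAt", "DivisionRate", function(rate, u) {
  y <- approx(rate@grid, rate@values, xout = u, rule = 2L)$y
  if (rate@extrapolation == "zero") {
    y[u > rate@grid[length(rate@grid)]] <- 0
    y[u < rate@grid[1L]] <- 0
  }
  y
})

#' @rdname divisionRateAt
setMethod("rateIndex", "DivisionRate", function(rate) rate@index)

#' @rdname divisionRateAt
setMethod("rateGrid", "DivisionRate", function(rate) rate@grid)

#' @rdname divisionRateAt
setMethod("rateValues", "DivisionRate", function(rate) rate@values)

#' @rdname divisionRateAt
setMethod("reliableSupport", "DivisionRate", function(rate) rate@reliable)

setMethod("show", "DivisionRate", function(object) {
  cat(sprintf(
    "DivisionRate (%s-indexed) on [%.3g, %.3g], %d nodes, max %.3g/min\n",
    object@index, min(object@grid), max(object@grid), length(object@grid),
    max(object@values)))
  cat(sprintf("  reliable support: %d/%d nodes; extrapolation: %s\n",
              sum(object@reliable), length(object@reliable),
              object@extrapolation))
})

## Dense cumulative hazard of an age-indexed rate; used to invert the
## survival function when sampling lifetimes. Returns list(a, Lambda, bEnd).
cumulativeHazard <- function(rate, n = 4096L) {
  aEnd <- max(rate@grid)
  a <- seq(0, aEnd, length.out = n)
  B <- divisionRateAt(rate, a)
  list(a = a, Lambda = cumtrapz(a, B),
       bEnd = if (rate@extrapolation == "constant") B[n] else 0)
}

## Invert Lambda(a) = E (vector E of Exp(1) draws) -> ages.
## Errors with "divergent lifetime" if the hazard cannot accumulate enough.
invertCumHazard <- function(ch, E) {
  LEnd <- ch$Lambda[length(ch$Lambda)]
  a <- approx(ch$Lambda, ch$a, xout = pmin(E, LEnd), ties = "ordered")$y
  over <- E > LEnd
  if (any(over)) {
    if (ch$bEnd <= 0)
      stopf("divergent lifetime: hazard exhausted at %.3g with survival mass left",
            max(ch$a))
    a[over] <- max(ch$a) + (E[over] - LEnd) / ch$bEnd
  }
  a
}

## For sizer control with pure exponential growth v(x) = v*x:
## cumulative hazard along a trajectory from birth size xb to size x is
## (H(x) - H(xb)) / v_i with H(x) = int B_s(u)/u du. Precompute H on a dense
## grid together with its inverse; constant-B continuation beyond the grid
## gives the analytic tail H = H_end + B_end * log(x/x_end).
sizeHazardPrimitive <- function(rate, xLow = NULL, n = 8192L) {
  gEnd <- max(rate@grid)
  if (is.null(xLow)) xLow <- max(min(rate@grid[rate@grid > 0], gEnd / n), gEnd / n)
  x <- exp(seq(log(xLow), log(gEnd), length.out = n))
  B <- divisionRateAt(rate, x)
  H <- cumtrapz(log(x), B)  # int B dlog(x) = int B/u du
  list(x = x, H = H,
       bEnd = if (rate@extrapolation == "constant") B[n] else 0)
}

## Invert H at targets; errors when the tail hazard is zero and the target
## exceeds the accumulated hazard ("divergent lifetime").
invertSizeHazard <- function(sh, Htarget) {
  HEnd <- sh$H[length(sh$H)]
  out <- approx(sh$H, sh$x, xout = pmin(Htarget, HEnd), ties = "ordered")$y
  over <- Htarget > HEnd
  if (any(over)) {
    if (sh$bEnd <= 0)
      stopf("divergent lifetime: size hazard exhausted at %.3g um", max(sh$x))
    out[over] <- max(sh$x) * exp((Htarget[over] - HEnd) / sh$bEnd)
  }
  out
}

## Evaluate H (with analytic tail) at sizes.
evalSizeHazardPrimitive <- function(sh, x) {
  HEnd <- sh$H[length(sh$H)]
  H <- approx(sh$x, sh$H, xout = pmin(x, max(sh$x)), rule = 2L, ties = "ordered")$y
  over <- x > max(sh$x)
  if (any(over)) H[over] <- HEnd + sh$bEnd * log(x[over] / max(sh$x))
  H
}
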