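#' @import methods
#' @importFrom stats approx bw.nrd0 coef cor dnorm lm optimize pnorm qnorm
#'   quantile rbinom rlnorm rnorm runif sd shapiro.test var
#' @importFrom utils head tail
#' @importFrom data.table data.table as.data.table setDT setDF fread fwrite
#'   := .N .SD setorder rbindlist
NULL

## Trapezoidal quadrature on a (uniform or not) grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## Cumulative trapezoidal integral, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

## 2-D trapezoid on a tensor grid; z is length(x) x length(y).
trapz2 <- function(x, y, z) {
  trapz(y, apply(z, 2L, function(col) trapz(x, col)))
}

## Cell-centered uniform grid with K cells on [0, upper]:
## centers at (k - 1/2) * upper / K.
cellCenters <- function(upper, K) {
  h <- upper / K
  seq(h / 2, by = h, length.out = K)
}

## Truncated Gaussian draws by inverse-CDF (deterministic uniform count, so
## the stream position does not depend on rejection luck).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

## Linear interpolation with constant extrapolation on the right and a
## configurable left fill (used by DivisionRate lookups).
interpConst <- function(xgrid, ygrid, x, leftFill = ygrid[1L]) {
  y <- approx(xgrid, ygrid, xout = x, rule = 2L)$y
  y[x < xgrid[1L]] <- leftFill
  y
}

## data.table non-standard evaluation symbols
utils::globalVariables(c(
  ".", "cell_id", "parent_id", "time_min", "length_um", "birth_time_min",
  "birth_size_um", "division_time_min", "division_size_um", "division_age_min",
  "growth_rate_per_min", "septum_ratio", "complete", "generation", "bin",
  "bin_center_um", "mean_increment_um", "sem_um", "len", "d", "row__", "age",
  "kid_sum", "n_kids", "last_length_um", "division_time", "division_age",
  "obs_division_time_min", "V1"))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
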