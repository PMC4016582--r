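#' @include growth-law.R division-rate.R
NULL

## Published single-cell growth constants for the two reference experimental
## setups: agar-pad microcolonies ("f1": full genealogical trees, 2-min
## acquisition, v = 0.0274/min, exponential core 2.3-5.3 um) and
## mother-machine microchannels ("s1": sparse trees, 1-min acquisition,
## v = 0.0317/min, core 3.5-7.2 um). The cubic coefficients interpolate the
## measured length-increment-versus-length curve outside the core range.
.presets <- list(
  f1 = list(rate = 0.0274, xMin = 2.3, xMax = 5.3,
            poly = c(0.13, -0.094, 0.036, -0.0033),
            acquisitionDt = 2),
  s1 = list(rate = 0.0317, xMin = 3.5, xMax = 7.2,
            poly = c(0.67, -0.33, 0.063, -0.0036),
            acquisitionDt = 1)
)

#' Preset growth laws for the reference experimental setups
#'
#' Growth laws built from the published constants of the two reference
#' single-cell datasets: exponential elongation (`v = 0.0274`/min for the
#' agar-pad setup `"f1"`, `0.0317`/min for the mother-machine setup `"s1"`)
#' on the core size range, with a configurable continuation outside it.
#'
#' @param dataset `"f1"` or `"s1"`.
#' @param cap continuation outside the core range: `"none"` (pure exponential
#'   everywhere, the Size Model assumption), `"constant"` (linear elongation
#'   at the boundary speed), or `"polynomial"` (the published cubic
#'   `max(p(x), 0)` interpolating the increment curve, the Age Model fit).
#' @return a [GrowthLaw].
#' @examples
#' presetGrowthLaw("f1", cap = "polynomial")
#' @export
presetGrowthLaw <- function(dataset = c("f1", "s1"),
                            cap = c("none", "constant", "polynomial")) {
  dataset <- match.arg(dataset)
  cap <- match.arg(cap)
  p <- .presets[[dataset]]
  if (cap == "none") return(growthLaw(p$rate))
  growthLaw(p$rate, xMin = p$xMin, xMax = p$xMax,
            capBelow = cap, capAbove = cap,
            polyBelow = p$poly, polyAbove = p$poly, clampZero = TRUE)
}

#' Reference division rates for simulation studies
#'
#' Parametric hazards used as study conditions for the synthetic lineages.
#' The sizer hazard is a steep power law \eqn{B_s(x) = 0.02 (x/3)^8} per min,
#' giving division sizes concentrated around 4 um and birth sizes around
#' 2 um under near-symmetric division at `v = 0.0274`/min (generation time
#' about 25 min). The timer hazard is a Weibull hazard
#' \eqn{B_a(a) = (k/\sigma)(a/\sigma)^{k-1}} with shape `k = 6` and scale
#' chosen so the mean division age matches the doubling time `log(2)/v`
#' (division-age CV about 19%, comparable to observed cycle-time spread).
#'
#' @param control `"sizer"` or `"timer"`.
#' @param rate core growth rate (1/min) the hazard is matched to.
#' @param upper grid upper bound (um for sizer, min for timer); defaults: 10
#'   um, 3 mean generation times.
#' @param n grid nodes.
#' @return a [DivisionRate].
#' @export
presetDivisionRate <- function(control = c("sizer", "timer"), rate = 0.0274,
                               upper = NULL, n = 512L) {
  control <- match.arg(control)
  if (control == "sizer") {
    if (is.null(upper)) upper <- 10
    tabulateDivisionRate(function(x) 0.02 * (x / 3)^8, "size", upper, n)
  } else {
    meanAge <- log(2) / rate
    k <- 6
    sigma <- meanAge / gamma(1 + 1 / k)
    if (is.null(upper)) upper <- 3 * meanAge
    tabulateDivisionRate(function(a) (k / sigma) * (a / sigma)^(k - 1),
                         "age", upper, n)
  }
}
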