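#' @include AllGenerics.R
NULL

#' Construct a growth law
#'
#' @param rate core exponential elongation rate v (1/min).
#' @param xMin,xMax core range bounds (um). With the default `0`/`Inf` the
#'   law is exponential everywhere.
#' @param capBelow,capAbove continuation type outside the core range:
#'   `"none"`, `"constant"`, `"linear"` or `"polynomial"` (see [GrowthLaw]).
#' @param polyBelow,polyAbove ascending-power coefficients for the
#'   linear/polynomial caps (speed in um/min as a function of size in um).
#' @param clampZero clamp cap speeds at zero (`max(p(x), 0)`).
#' @return a [GrowthLaw].
#' @examples
#' ## pure exponential elongation at 0.0274/min
#' growthLaw(0.0274)
#' ## exponential on [2.3, 5.3] um, constant speed outside
#' growthLaw(0.0274, xMin = 2.3, xMax = 5.3,
#'           capBelow = "constant", capAbove = "constant")
#' @export
growthLaw <- function(rate, xMin = 0, xMax = Inf,
                      capBelow = "none", capAbove = "none",
                      polyBelow = numeric(0), polyAbove = numeric(0),
                      clampZero = TRUE) {
  new("GrowthLaw", rate = rate, xMin = xMin, xMax = xMax,
      capBelow = capBelow, capAbove = capAbove,
      polyBelow = polyBelow, polyAbove = polyAbove,
      clampZero = clampZero)
}

polyEval <- function(coefs, x) {
  y <- rep(0, length(x))
  for (i in seq_along(coefs)) y <- y + coefs[i] * x^(i - 1L)
  y
}

#' @rdname growthRateAt
setMethod("growthRateAt", "GrowthLaw", function(law, x, scale = 1) {
  v <- law@rate
  out <- v * x
  below <- x < law@xMin
  above <- x > law@xMax
  capVal <- function(type, coefs, xs, xBound) {
    switch(type,
      none = v * xs,
      constant = rep(v * xBound, length(xs)),
      linear = polyEval(coefs[seq_len(2L)], xs),
      polynomial = polyEval(coefs, xs))
  }
  if (any(below))
    out[below] <- capVal(law@capBelow, law@polyBelow, x[below], law@xMin)
  if (any(above))
    out[above] <- capVal(law@capAbove, law@polyAbove, x[above], law@xMax)
  if (law@clampZero) out <- pmax(out, 0)
  out * scale
})

setMethod("show", "GrowthLaw", function(object) {
  core <- if (is.finite(object@xMax) || object@xMin > 0)
    sprintf("on [%.3g, %.3g] um", object@xMin, object@xMax) else "everywhere"
  cat(sprintf("GrowthLaw: v(x) = %.4g * x %s\n", object@rate, core))
  if (object@capBelow != "none")
    cat(sprintf("  below: %s cap\n", object@capBelow))
  if (object@capAbove != "none")
    cat(sprintf("  above: %s cap\n", object@capAbove))
})

## TRUE when the law is v(x) = v*x everywhere (closed forms available).
isPureExponential <- function(law) {
  (law@capBelow == "none" && law@capAbove == "none") ||
    (law@xMin <= 0 && !is.finite(law@xMax))
}

## TRUE when caps are analytic piecewise (none/constant): vectorized
## closed-form trajectories.
isPiecewiseAnalytic <- function(law) {
  law@capBelow %in% c("none", "constant") &&
    law@capAbove %in% c("none", "constant")
}

#' Size reached after growing for a given time
#'
#' Integrates dx/dt = scale * v(x) from initial size `x0` over time `t`.
#' Closed-form piecewise integration for `none`/`constant` caps; classical
#' RK4 with fine substeps otherwise.
#'
#' @param law a [GrowthLaw].
#' @param x0 initial sizes (um).
#' @param t elapsed times (min), recycled against `x0`.
#' @param scale individual-rate factors (v_i / v), recycled.
#' @return sizes (um).
#' @export
sizeAfter <- function(law, x0, t, scale = 1) {
  n <- max(length(x0), length(t), length(scale))
  x0 <- rep_len(x0, n); t <- rep_len(t, n); scale <- rep_len(scale, n)
  if (any(t < 0)) stopf("negative growth times")
  if (isPiecewiseAnalytic(law)) {
    v <- law@rate * scale
    x <- x0
    trem <- t
    ## phase 1: constant speed below xMin
    if (law@capBelow == "constant" && law@xMin > 0) {
      cB <- law@rate * law@xMin * scale
      need <- x < law@xMin & trem > 0
      if (any(need)) {
        t1 <- (law@xMin - x[need]) / cB[need]
        dt1 <- pmin(trem[need], t1)
        x[need] <- x[need] + cB[need] * dt1
        trem[need] <- trem[need] - dt1
      }
    }
    ## phase 2: exponential core (extends to 0 / Inf when the cap is "none")
    xU <- if (law@capAbove == "constant") law@xMax else Inf
    need <- trem > 0 & x < xU
    if (any(need)) {
      t2 <- log(xU / x[need]) / v[need]
      dt2 <- pmin(trem[need], t2)
      x[need] <- x[need] * exp(v[need] * dt2)
      trem[need] <- trem[need] - dt2
    }
    ## phase 3: constant speed above xMax
    if (law@capAbove == "constant") {
      cA <- law@rate * law@xMax * scale
      need <- trem > 0
      if (any(need)) x[need] <- x[need] + cA[need] * trem[need]
    }
    return(x)
  }
  ## general caps: vectorized RK4, per-cell step h_i = t_i / N
  N <- max(8L, ceiling(max(t) / 0.25))
  h <- t / N
  x <- x0
  f <- function(xx) growthRateAt(law, xx, scale = 1) * scale
  for (i in seq_len(N)) {
    k1 <- f(x)
    k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}
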