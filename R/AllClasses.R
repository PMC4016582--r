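#' @include utils.R
NULL

#' Single-cell growth law v(x)
#'
#' Deterministic growth speed of cell length: exponential elongation
#' \eqn{v(x) = v x} on the core range \eqn{[x_{min}, x_{max}]}, with
#' configurable continuations ("caps") outside that range. Caps exist because
#' exactly exponential growth of arbitrarily small or large cells is
#' biologically meaningless and, under timer control, forbids a stable size
#' distribution; the behaviour of rare cells outside the observable range is
#' an assumption, not a measurement.
#'
#' @slot rate core exponential rate v (1/min).
#' @slot xMin,xMax bounds (um) of the exponential core range.
#' @slot capBelow,capAbove continuation type below/above the core range:
#'   `"none"` (exponential everywhere), `"constant"` (constant speed equal to
#'   the core speed at the boundary), `"linear"` (affine in x, coefficients in
#'   `polyBelow`/`polyAbove` as c(intercept, slope)), or `"polynomial"`
#'   (polynomial in x, ascending coefficients).
#' @slot polyBelow,polyAbove numeric coefficient vectors (ascending powers)
#'   for the `"linear"`/`"polynomial"` caps; ignored otherwise.
#' @slot clampZero clamp the cap at zero, i.e. use max(p(x), 0).
#' @aliases GrowthLaw
#' @exportClass GrowthLaw
setClass("GrowthLaw",
  representation(
    rate = "numeric", xMin = "numeric", xMax = "numeric",
    capBelow = "character", capAbove = "character",
    polyBelow = "numeric", polyAbove = "numeric",
    clampZero = "logical"
  ),
  prototype(
    rate = 0.0274, xMin = 0, xMax = Inf,
    capBelow = "none", capAbove = "none",
    polyBelow = numeric(0), polyAbove = numeric(0),
    clampZero = TRUE
  )
)

setValidity("GrowthLaw", function(object) {
  caps <- c("none", "constant", "linear", "polynomial")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    return("rate must be a single positive number")
  if (object@xMin < 0 || object@xMax <= object@xMin)
    return("need 0 <= xMin < xMax")
  if (!object@capBelow %in% caps || !object@capAbove %in% caps)
    return(sprintf("cap types must be one of %s", paste(caps, collapse = ", ")))
  if (object@capBelow %in% c("linear", "polynomial") && length(object@polyBelow) < 1L)
    return("polyBelow coefficients required for the chosen capBelow")
  if (object@capAbove %in% c("linear", "polynomial") && length(object@polyAbove) < 1L)
    return("polyAbove coefficients required for the chosen capAbove")
  TRUE
})

#' Nonparametric division rate (hazard) on a grid
#'
#' Tabulated instantaneous division probability per unit time, indexed by cell
#' age or cell size. `B(u) dt` is the probability that a cell at age/size `u`
#' divides within `dt`. Values between grid nodes are linearly interpolated;
#' outside the grid the declared extrapolation rule applies (constant
#' continuation at the edge value, or zero).
#'
#' @slot index `"age"` or `"size"`.
#' @slot grid strictly increasing nonnegative grid (min or um).
#' @slot values nonnegative, finite rates (1/min), same length as `grid`.
#' @slot reliable logical mask marking grid nodes where the estimate is
#'   supported by data (survival / at-risk fraction above threshold).
#' @slot extrapolation `"constant"` or `"zero"`: rule beyond the grid; below
#'   the grid the rate is the first value (`"constant"`) or zero.
#' @aliases DivisionRate
#' @exportClass DivisionRate
setClass("DivisionRate",
  representation(
    index = "character", grid = "numeric", values = "numeric",
    reliable = "logical", extrapolation = "character"
  )
)

setValidity("DivisionRate", function(object) {
  if (!object@index %in% c("age", "size"))
    return("index must be 'age' or 'size'")
  if (length(object@grid) < 2L || any(diff(object@grid) <= 0))
    return("grid must be strictly increasing with >= 2 nodes")
  if (any(object@grid < 0)) return("grid must be nonnegative")
  if (length(object@values) != length(object@grid))
    return("values and grid lengths differ")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("rates must be finite and nonnegative")
  if (length(object@reliable) != length(object@grid))
    return("reliable mask and grid lengths differ")
  if (!object@extrapolation %in% c("constant", "zero"))
    return("extrapolation must be 'constant' or 'zero'")
  TRUE
})

#' Density on a cell-centered grid
#'
#' A (possibly multivariate) probability density tabulated on uniform
#' cell-centered grids. Axes are named (`age`, `size`, `rate`); `values` has
#' one dimension per axis. When `normalized`, the trapezoidal integral over
#' all axes is 1 (within 1e-3; solver outputs reach 1e-6).
#'
#' @slot axes named list of numeric axis grids.
#' @slot values numeric array, `dim == lengths(axes)` (a vector for one axis).
#' @slot normalized logical flag.
#' @aliases DensityGrid
#' @exportClass DensityGrid
setClass("DensityGrid",
  representation(axes = "list", values = "array", normalized = "logical")
)

setValidity("DensityGrid", function(object) {
  if (length(object@axes) < 1L || is.null(names(object@axes)) ||
      any(!nzchar(names(object@axes))))
    return("axes must be a named list")
  dims <- vapply(object@axes, length, 1L)
  vd <- dim(object@values)
  if (is.null(vd)) vd <- length(object@values)
  if (!identical(as.integer(vd), as.integer(dims)))
    return("dim(values) must match axis lengths")
  if (any(!is.finite(object@values)) || any(object@values < -1e-12))
    return("density values must be finite and nonnegative")
  for (ax in object@axes)
    if (length(ax) < 2L || any(diff(ax) <= 0))
      return("each axis must be strictly increasing with >= 2 nodes")
  TRUE
})

#' Stable distribution of a structured-population model
#'
#' Principal output of the growth-fragmentation solvers: the normalized stable
#' (eigen-)distribution N together with the Malthus coefficient lambda, so
#' that the population density behaves as \eqn{n(t, \cdot) \approx
#' e^{\lambda t} N(\cdot)} after transients.
#'
#' @slot density [DensityGrid] with the full solution (age x size, size, or
#'   size x rate depending on the model).
#' @slot malthus Malthus coefficient lambda (1/min), averaged over the final
#'   iterations.
#' @slot ageMarginal,sizeMarginal [DensityGrid] marginals (size marginal always
#'   present; age marginal only for age-structured runs).
#' @slot residual final sup-norm change between successive renormalized
#'   iterates.
#' @slot iterations number of time steps taken.
#' @slot converged whether `residual <= tol` was reached.
#' @slot leakage fraction of per-step mass lost through the open domain
#'   boundaries at the final iterate (diagnostic; should be tiny).
#' @aliases StableDistribution
#' @exportClass StableDistribution
setClass("StableDistribution",
  representation(
    density = "DensityGrid", malthus = "numeric",
    ageMarginal = "ANY", sizeMarginal = "ANY",
    residual = "numeric", iterations = "integer",
    converged = "logical", leakage = "numeric"
  )
)

#' Simulation configuration for cell lineages
#'
#' Bundles the generative law for the stochastic lineage simulator: control
#' law (which index the division hazard reads), division rate, growth law,
#' phenotypic noise levels, observation topology and acquisition settings.
#'
#' See [simConfig()] for construction with defaults and the vignette for the
#' rationale behind the default noise levels (8% growth-rate CV, 4% septum
#' CV, near-symmetric division).
#'
#' @aliases SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    controlLaw = "character", divisionRate = "DivisionRate",
    growthLaw = "GrowthLaw", meanRate = "numeric", rateCV = "numeric",
    septumCV = "numeric", topology = "character", duration = "numeric",
    generations = "integer", nChannels = "integer",
    initialMeanLog = "numeric", initialSdLog = "numeric",
    acquisitionDt = "numeric", lengthNoiseCV = "numeric",
    divisionTimeNoiseCV = "numeric", seed = "integer",
    maxCells = "integer", nInitial = "integer", burnin = "integer"
  )
)

setValidity("SimConfig", function(object) {
  if (!object@controlLaw %in% c("timer", "sizer"))
    return("controlLaw must be 'timer' or 'sizer'")
  if (!object@topology %in% c("full_tree", "sparse_tree"))
    return("topology must be 'full_tree' or 'sparse_tree'")
  wantIndex <- if (object@controlLaw == "timer") "age" else "size"
  if (object@divisionRate@index != wantIndex)
    return(sprintf("controlLaw '%s' needs a division rate indexed by %s",
                   object@controlLaw, wantIndex))
  if (object@acquisitionDt <= 0) return("acquisitionDt must be positive")
  cvs <- c(object@rateCV, object@septumCV, object@lengthNoiseCV,
           object@divisionTimeNoiseCV)
  if (any(cvs < 0)) return("all CVs must be nonnegative")
  if (object@meanRate <= 0) return("meanRate must be positive")
  if (object@topology == "full_tree" &&
      (!is.finite(object@duration) || object@duration <= 0))
    return("full_tree needs a positive duration")
  if (object@topology == "sparse_tree" && object@generations < 1L)
    return("sparse_tree needs generations >= 1")
  if (object@nChannels < 1L) return("nChannels must be >= 1")
  if (object@maxCells < 2L) return("maxCells must be >= 2")
  TRUE
})

#' Goodness-of-fit distance between two densities
#'
#' Normalized integrated squared error between two densities on a common
#' grid: \eqn{D = \sqrt{\int (f-g)^2 / \int f^2}}, reported as a percentage.
#' `f` is the reference (experimental) density.
#'
#' @slot pct the distance in percent.
#' @slot numerator,denominator the two integrals.
#' @slot gridSpec character summary of the common grid.
#' @aliases FitDistance
#' @exportClass FitDistance
setClass("FitDistance",
  representation(pct = "numeric", numerator = "numeric",
                 denominator = "numeric", gridSpec = "character")
)

#' Timer-versus-sizer model evaluation report
#'
#' Output of [evaluateModels()]: distances of the timer (Age Model) and sizer
#' (Size Model) reconstructions from the empirical age-size distribution, the
#' age-at-division versus size-at-birth correlation diagnostic, the estimated
#' division rates, growth summary, and the preferred model.
#'
#' @slot dAge,dSize [FitDistance] of the Age / Size Model reconstruction.
#' @slot correlation Pearson correlation between division age and birth size.
#' @slot correlationP permutation p-value for the correlation.
#' @slot rateAge,rateSize estimated [DivisionRate] objects.
#' @slot growthRate mean single-cell exponential rate (1/min).
#' @slot growthLawTimer the capped [GrowthLaw] used for the Age Model.
#' @slot empirical [DensityGrid], empirical age-size KDE.
#' @slot timerFit,sizerFit [StableDistribution] reconstructions.
#' @slot preferred `"timer"` or `"sizer"` (argmin of the two distances).
#' @slot nCycles number of complete cycles used.
#' @slot seed RNG seed recorded for provenance.
#' @aliases FitReport
#' @exportClass FitReport
setClass("FitReport",
  representation(
    dAge = "FitDistance", dSize = "FitDistance",
    correlation = "numeric", correlationP = "numeric",
    rateAge = "DivisionRate", rateSize = "DivisionRate",
    growthRate = "numeric", growthLawTimer = "GrowthLaw",
    empirical = "DensityGrid",
    timerFit = "StableDistribution", sizerFit = "StableDistribution",
    preferred = "character", nCycles = "integer", seed = "integer"
  )
)
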