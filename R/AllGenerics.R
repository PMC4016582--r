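#' @include AllClasses.R
NULL

#' Evaluate a growth law
#'
#' @param law a [GrowthLaw].
#' @param x sizes (um).
#' @param scale multiplicative individual-rate factor (v_i / v); scales the
#'   whole speed field.
#' @return growth speeds dx/dt (um/min), same length as `x`.
#' @export
setGeneric("growthRateAt", function(law, x, scale = 1) standardGeneric("growthRateAt"))

#' Evaluate a division rate
#'
#' @param rate a [DivisionRate].
#' @param u ages (min) or sizes (um), matching `rateIndex(rate)`.
#' @return hazards (1/min), linearly interpolated with the object's
#'   extrapolation rule outside the grid.
#' @export
setGeneric("divisionRateAt", function(rate, u) standardGeneric("divisionRateAt"))

#' @rdname divisionRateAt
#' @export
setGeneric("rateIndex", function(rate) standardGeneric("rateIndex"))

#' @rdname divisionRateAt
#' @export
setGeneric("rateGrid", function(rate) standardGeneric("rateGrid"))

#' @rdname divisionRateAt
#' @export
setGeneric("rateValues", function(rate) standardGeneric("rateValues"))

#' @rdname divisionRateAt
#' @export
setGeneric("reliableSupport", function(rate) standardGeneric("reliableSupport"))

#' Access density grids
#'
#' @param x a [DensityGrid] (or [StableDistribution] for marginals).
#' @param axis axis name for `gridAxis`.
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))

#' @rdname densityValues
#' @export
setGeneric("gridAxis", function(x, axis) standardGeneric("gridAxis"))

#' @rdname densityValues
#' @export
setGeneric("gridIntegral", function(x) standardGeneric("gridIntegral"))

#' @rdname densityValues
#' @param axis name of the axis to keep.
#' @export
setGeneric("marginalDensity", function(x, axis) standardGeneric("marginalDensity"))

#' Access solver results
#'
#' @param x a [StableDistribution].
#' @export
setGeneric("malthusCoefficient", function(x) standardGeneric("malthusCoefficient"))

#' @rdname malthusCoefficient
#' @export
setGeneric("sizeMarginal", function(x) standardGeneric("sizeMarginal"))

#' @rdname malthusCoefficient
#' @export
setGeneric("ageMarginal", function(x) standardGeneric("ageMarginal"))

#' Access fit distances
#'
#' @param x a [FitDistance] or [FitReport].
#' @export
setGeneric("distancePct", function(x) standardGeneric("distancePct"))

#' @rdname distancePct
#' @export
setGeneric("preferredModel", function(x) standardGeneric("preferredModel"))
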