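#' @include AllGenerics.R
NULL

#' Construct a density grid
#'
#' @param values numeric vector/matrix/array of nonnegative density values.
#' @param ... named axes (e.g. `age = , size = `), one per dimension of
#'   `values`, in dimension order.
#' @param normalize divide by the trapezoidal integral (default `TRUE`).
#' @return a [DensityGrid].
#' @export
densityGrid <- function(values, ..., normalize = TRUE) {
  axes <- list(...)
  vals <- values
  if (is.null(dim(vals))) vals <- array(as.numeric(vals), dim = length(vals))
  if (normalize) {
    tot <- gridIntegralRaw(axes, vals)
    if (!is.finite(tot) || tot <= 0)
      stopf("cannot normalize a density with integral %.3g", tot)
    vals <- vals / tot
  }
  new("DensityGrid", axes = axes, values = vals, normalized = normalize)
}

trapzWeights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1L] <- dx[1L] / 2
  w[n] <- dx[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dx[-1L] + dx[-(n - 1L)]) / 2
  w
}

## Trapezoidal integral over all axes (tensor-product weights).
gridIntegralRaw <- function(axes, vals) {
  w <- trapzWeights(axes[[1L]])
  if (length(axes) > 1L)
    for (d in 2:length(axes)) w <- outer(w, trapzWeights(axes[[d]]))
  sum(w * vals)
}

#' @rdname densityValues
setMethod("densityValues", "DensityGrid", function(x) {
  v <- x@values
  if (length(x@axes) == 1L) as.numeric(v) else v
})

#' @rdname densityValues
setMethod("gridAxis", "DensityGrid", function(x, axis) {
  if (!axis %in% names(x@axes))
    stopf("no axis '%s' (have: %s)", axis, paste(names(x@axes), collapse = ", "))
  x@axes[[axis]]
})

#' @rdname densityValues
setMethod("gridIntegral", "DensityGrid", function(x) {
  gridIntegralRaw(x@axes, x@values)
})

#' @rdname densityValues
setMethod("marginalDensity", "DensityGrid", function(x, axis) {
  keep <- match(axis, names(x@axes))
  if (is.na(keep))
    stopf("no axis '%s' (have: %s)", axis, paste(names(x@axes), collapse = ", "))
  if (length(x@axes) == 1L) return(x)
  vals <- x@values
  drop <- setdiff(seq_along(x@axes), keep)
  for (d in rev(drop)) {
    w <- trapzWeights(x@axes[[d]])
    vals <- applyAxisSum(vals, d, w)
  }
  new("DensityGrid", axes = stats::setNames(list(x@axes[[keep]]), axis),
      values = array(as.numeric(vals), dim = length(vals)),
      normalized = x@normalized)
})

## Weighted sum of an array along axis d (contraction with weight vector w).
applyAxisSum <- function(vals, d, w) {
  dm <- dim(vals)
  if (is.null(dm)) dm <- length(vals)
  if (length(dm) == 1L) return(sum(vals * w))
  perm <- c(setdiff(seq_along(dm), d), d)
  m <- aperm(vals, perm)
  dim(m) <- c(prod(dm[perm[-length(perm)]]), dm[d])
  out <- as.numeric(m %*% w)
  array(out, dim = dm[perm[-length(perm)]])
}

setMethod("show", "DensityGrid", function(object) {
  dims <- paste(vapply(object@axes, length, 1L), collapse = " x ")
  cat(sprintf("DensityGrid over %s (%s nodes), integral %.6f%s\n",
              paste(names(object@axes), collapse = " x "), dims,
              gridIntegral(object),
              if (object@normalized) " (normalized)" else ""))
})
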