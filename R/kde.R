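#' @include density-grid.R
NULL

#' One-dimensional kernel density estimate with boundary reflection
#'
#' Gaussian-kernel estimate on a fixed grid with reflection at zero (ages and
#' sizes are nonnegative, so kernel mass that would leak below zero is folded
#' back), renormalized on the grid by trapezoidal quadrature.
#'
#' @param sample numeric sample (n >= 2, non-constant).
#' @param grid evaluation grid (strictly increasing); default: 2^7
#'   cell-centered nodes on `[0, max(sample)]`.
#' @param bw bandwidth; default Silverman's rule ([stats::bw.nrd0()]).
#' @param axis axis name for the returned [DensityGrid] (`"size"`, `"age"`...).
#' @param weights optional nonnegative observation weights (occupation
#'   measures half-weight each cell's birth frame; see
#'   [occupationMeasure()]).
#' @return a normalized [DensityGrid].
#' @export
kde1d <- function(sample, grid = NULL, bw = NULL, axis = "size",
                  weights = NULL) {
  keep <- is.finite(sample)
  sample <- sample[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(sample) < 2L) stopf("kde1d needs at least 2 finite observations")
  if (var(sample) == 0) stopf("kde1d: sample is constant (zero variance)")
  if (is.null(grid)) grid <- cellCenters(max(sample), 2L^7L)
  if (is.null(bw)) bw <- bw.nrd0(sample)
  dens <- kdeReflect1(sample, grid, bw, weights = weights)
  tot <- trapz(grid, dens)
  if (!is.finite(tot) || tot <= 0) stopf("kde1d: degenerate density")
  new("DensityGrid", axes = stats::setNames(list(grid), axis),
      values = array(dens / tot, dim = length(dens)), normalized = TRUE)
}

## Raw reflected-Gaussian density values on a grid (no normalization),
## evaluated in chunks to bound memory for large samples.
kdeReflect1 <- function(sample, grid, bw, chunk = 50000L, weights = NULL) {
  n <- length(sample)
  if (is.null(weights)) weights <- rep(1, n)
  dens <- numeric(length(grid))
  for (i0 in seq(1L, n, by = chunk)) {
    ii <- i0:min(n, i0 + chunk - 1L)
    s <- sample[ii]
    ## reflection at 0: K(g - s) + K(g + s)
    d <- outer(grid, s, function(g, x) dnorm(g - x, sd = bw) + dnorm(g + x, sd = bw))
    dens <- dens + as.numeric(d %*% weights[ii])
  }
  dens / sum(weights)
}

#' Smooth a gridded density with a Gaussian kernel
#'
#' Convolves a [DensityGrid] with the same reflected-Gaussian kernel used by
#' [kde1d()]/[kde2d()], then renormalizes. Passing a model density through
#' the identical smoothing operator makes it directly comparable to a kernel
#' density estimate of data (both then represent the underlying distribution
#' convolved with the same kernel), which removes the smoothing bias from
#' model-versus-simulation distance checks.
#'
#' @param dg a [DensityGrid].
#' @param bw named bandwidths per axis (e.g. `c(age = 2, size = 0.1)`);
#'   axes without an entry are left unsmoothed.
#' @return a normalized [DensityGrid] on the same grid.
#' @export
smoothDensity <- function(dg, bw) {
  vals <- dg@values
  for (ax in names(bw)) {
    i <- match(ax, names(dg@axes))
    if (is.na(i)) stopf("no axis '%s'", ax)
    g <- dg@axes[[i]]
    S <- outer(g, g, function(x, y) dnorm(x - y, sd = bw[[ax]]) +
                 dnorm(x + y, sd = bw[[ax]]))
    S <- S * rep(trapzWeights(g), each = length(g))
    ## contract axis i with the smoothing operator
    perm <- c(i, setdiff(seq_along(dim(vals) %||% length(vals)), i))
    dm <- dim(vals); if (is.null(dm)) dm <- length(vals)
    m <- if (length(dm) == 1L) matrix(vals, ncol = 1L) else {
      a <- aperm(vals, perm); dim(a) <- c(dm[i], prod(dm[-i])); a
    }
    sm <- S %*% m
    if (length(dm) == 1L) vals <- array(as.numeric(sm), dim = dm) else {
      dim(sm) <- dm[perm]
      vals <- aperm(sm, order(perm))
    }
  }
  tot <- gridIntegralRaw(dg@axes, vals)
  new("DensityGrid", axes = dg@axes, values = vals / tot, normalized = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bivariate kernel density estimate on a regular grid
#'
#' Product-Gaussian kernel estimate of the joint age-size distribution from
#' the occupation measure (the (age, size) of every cell at every time step),
#' with reflection at `age = 0` and `size = 0`, evaluated on a 2^7 x 2^7
#' cell-centered grid and renormalized.
#'
#' @param age,size coordinates of the observations (same length, n >= 10).
#' @param ageGrid,sizeGrid evaluation grids; defaults: 2^7 cell-centered
#'   nodes on `[0, max(age)]` and `[0, max(size)]`.
#' @param bwAge,bwSize per-axis bandwidths; default Silverman's rule.
#' @param weights optional nonnegative observation weights.
#' @return a normalized [DensityGrid] with axes `age`, `size`.
#' @export
kde2d <- function(age, size, ageGrid = NULL, sizeGrid = NULL,
                  bwAge = NULL, bwSize = NULL, weights = NULL) {
  keep <- is.finite(age) & is.finite(size)
  age <- age[keep]; size <- size[keep]
  n <- length(age)
  if (is.null(weights)) weights <- rep(1, n) else weights <- weights[keep]
  if (n < 10L) stopf("kde2d needs at least 10 observations")
  if (var(age) == 0 || var(size) == 0)
    stopf("kde2d: degenerate (rank-deficient) point cloud")
  if (is.null(ageGrid)) ageGrid <- cellCenters(max(age), 2L^7L)
  if (is.null(sizeGrid)) sizeGrid <- cellCenters(max(size), 2L^7L)
  if (is.null(bwAge)) bwAge <- bw.nrd0(age)
  if (is.null(bwSize)) bwSize <- bw.nrd0(size)
  if (n > 20000L) {
    ## binned evaluation: accumulate a fine weighted histogram (4x the
    ## output resolution; bin width far below any plausible bandwidth) and
    ## convolve it with the reflected kernel matrices
    nfA <- 4L * length(ageGrid); nfS <- 4L * length(sizeGrid)
    fa <- cellCenters(max(age) * (1 + 1e-9), nfA)
    fs <- cellCenters(max(size) * (1 + 1e-9), nfS)
    ia <- pmin(pmax(1L, findInterval(age, fa - (fa[2L] - fa[1L]) / 2)), nfA)
    is <- pmin(pmax(1L, findInterval(size, fs - (fs[2L] - fs[1L]) / 2)), nfS)
    idx <- (is - 1L) * nfA + ia
    agg <- rowsum(weights, idx)
    H <- matrix(0, nfA, nfS)
    H[as.integer(rownames(agg))] <- agg[, 1L]
    A <- outer(ageGrid, fa,
               function(g, x) dnorm(g - x, sd = bwAge) + dnorm(g + x, sd = bwAge))
    S <- outer(sizeGrid, fs,
               function(g, x) dnorm(g - x, sd = bwSize) + dnorm(g + x, sd = bwSize))
    dens <- (A %*% H %*% t(S)) / sum(weights)
    return(densityGrid(dens, age = ageGrid, size = sizeGrid, normalize = TRUE))
  }
  dens <- matrix(0, length(ageGrid), length(sizeGrid))
  chunk <- 20000L
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1L)
    A <- outer(ageGrid, age[idx],
               function(g, x) dnorm(g - x, sd = bwAge) + dnorm(g + x, sd = bwAge))
    S <- outer(sizeGrid, size[idx],
               function(g, x) dnorm(g - x, sd = bwSize) + dnorm(g + x, sd = bwSize))
    dens <- dens + tcrossprod(A * rep(weights[idx], each = length(ageGrid)), S)
  }
  dens <- dens / sum(weights)
  densityGrid(dens, age = ageGrid, size = sizeGrid, normalize = TRUE)
}
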