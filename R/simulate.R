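#' @include presets.R
NULL

#' Build a simulation configuration
#'
#' Assembles the generative law for the stochastic lineage simulator. A cell
#' born with size `x_b` draws an individual elongation rate `v_i` (truncated
#' Gaussian around `meanRate` with CV `rateCV`), grows deterministically
#' under `growthLaw` scaled by `v_i/meanRate`, and divides with hazard
#' `divisionRate` read on its age (`controlLaw = "timer"`) or size
#' (`"sizer"`). At division a septum fraction `theta` is drawn (truncated
#' Gaussian around 1/2 with CV `septumCV`, support (0.2, 0.8)); the daughters
#' receive `theta * x_d` and `(1 - theta) * x_d`.
#'
#' Defaults emulate the agar-pad reference conditions: `v = 0.0274`/min,
#' 8% growth-rate CV, 4% septum CV, 2-min acquisition for full trees (1 min
#' for mother-machine runs), lengths of a few um.
#'
#' @param controlLaw `"sizer"` or `"timer"`.
#' @param divisionRate a [DivisionRate] whose index matches `controlLaw`
#'   (default: [presetDivisionRate()] for that law).
#' @param growthLaw a [GrowthLaw] (default pure exponential at `meanRate`).
#' @param meanRate mean individual growth rate (1/min).
#' @param rateCV,septumCV phenotypic noise CVs (fractions).
#' @param topology `"full_tree"` (all descendants kept, duration-limited) or
#'   `"sparse_tree"` (mother-machine: one daughter followed per division).
#' @param duration full-tree simulation length (min).
#' @param generations sparse-tree generations followed per channel.
#' @param nChannels number of mother-machine channels (sparse only).
#' @param initialMeanLog,initialSdLog log-normal initial birth-size
#'   parameters (um scale).
#' @param acquisitionDt frame interval (min).
#' @param lengthNoiseCV,divisionTimeNoiseCV measurement-noise CVs used by
#'   [applyMeasurementLayer()].
#' @param seed integer RNG seed; identical configurations give bit-identical
#'   tables.
#' @param maxCells full-tree population cap (error beyond it).
#' @param nInitial number of founder cells (full tree).
#' @param burnin generations discarded by [simulateCycles()] to approximate
#'   the stable regime.
#' @return a validated [SimConfig].
#' @export
simConfig <- function(controlLaw = c("sizer", "timer"),
                      divisionRate = NULL, growthLaw = NULL,
                      meanRate = 0.0274, rateCV = 0.08, septumCV = 0.04,
                      topology = c("full_tree", "sparse_tree"),
                      duration = 400, generations = 40L, nChannels = 100L,
                      initialMeanLog = log(2), initialSdLog = 0.15,
                      acquisitionDt = NULL, lengthNoiseCV = 0,
                      divisionTimeNoiseCV = 0, seed = 1L,
                      maxCells = 200000L, nInitial = 1L, burnin = 5L) {
  controlLaw <- match.arg(controlLaw)
  topology <- match.arg(topology)
  if (is.null(divisionRate))
    divisionRate <- presetDivisionRate(controlLaw, rate = meanRate)
  if (is.null(growthLaw)) growthLaw <- growthLaw(meanRate)
  if (is.null(acquisitionDt))
    acquisitionDt <- if (topology == "full_tree") 2 else 1
  new("SimConfig", controlLaw = controlLaw, divisionRate = divisionRate,
      growthLaw = growthLaw, meanRate = meanRate, rateCV = rateCV,
      septumCV = septumCV, topology = topology, duration = as.numeric(duration),
      generations = as.integer(generations), nChannels = as.integer(nChannels),
      initialMeanLog = initialMeanLog, initialSdLog = initialSdLog,
      acquisitionDt = acquisitionDt, lengthNoiseCV = lengthNoiseCV,
      divisionTimeNoiseCV = divisionTimeNoiseCV, seed = as.integer(seed),
      maxCells = as.integer(maxCells), nInitial = as.integer(nInitial),
      burnin = as.integer(burnin))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %s control, %s topology\n",
              object@controlLaw, object@topology))
  cat(sprintf("  v = %.4g/min (CV %.2g), septum CV %.2g, dt = %.3g min, seed %d\n",
              object@meanRate, object@rateCV, object@septumCV,
              object@acquisitionDt, object@seed))
})

## Draw individual growth rates: truncated Gaussian, +/- 3 sigma and
## positive.
drawRates <- function(n, cfg) {
  v <- cfg@meanRate; cv <- cfg@rateCV
  if (cv == 0) return(rep(v, n))
  rtruncnorm(n, v, cv * v, lower = max(v * (1 - 3 * cv), 0.05 * v),
             upper = v * (1 + 3 * cv))
}

## Draw septum fractions: truncated Gaussian around 1/2 on (0.2, 0.8).
drawSeptum <- function(n, cfg) {
  if (cfg@septumCV == 0) return(rep(0.5, n))
  rtruncnorm(n, 0.5, 0.5 * cfg@septumCV, lower = 0.2, upper = 0.8)
}

## Per-call caches of the hazard primitives.
hazardCache <- function(cfg) {
  if (cfg@controlLaw == "timer") {
    list(ch = cumulativeHazard(cfg@divisionRate))
  } else if (isPureExponential(cfg@growthLaw)) {
    list(sh = sizeHazardPrimitive(cfg@divisionRate))
  } else {
    list()
  }
}

## Sample one cycle for each (xb, vi): returns list(age, xd).
sampleCycleBatch <- function(cfg, cache, xb, vi) {
  n <- length(xb)
  E <- -log(runif(n))  # Exp(1) via a single uniform each, fixed stream use
  if (cfg@controlLaw == "timer") {
    age <- invertCumHazard(cache$ch, E)
    xd <- sizeAfter(cfg@growthLaw, xb, age, scale = vi / cfg@meanRate)
    return(list(age = age, xd = xd))
  }
  if (!is.null(cache$sh)) {
    ## sizer + pure exponential growth: closed-form hazard primitive
    H0 <- evalSizeHazardPrimitive(cache$sh, xb)
    xd <- invertSizeHazard(cache$sh, H0 + vi * E)
    xd <- pmax(xd, xb * (1 + 1e-12))
    age <- log(xd / xb) / vi
    return(list(age = age, xd = xd))
  }
  ## sizer + general growth law: step the trajectory and accumulate hazard
  dt <- 0.25
  horizon <- 60 * log(2) / cfg@meanRate
  x <- xb; Lam <- numeric(n); t <- numeric(n)
  age <- rep(NA_real_, n); xd <- rep(NA_real_, n)
  Bcur <- divisionRateAt(cfg@divisionRate, x)
  alive <- rep(TRUE, n)
  while (any(alive)) {
    xNew <- sizeAfter(cfg@growthLaw, x[alive], dt, scale = vi[alive] / cfg@meanRate)
    Bnew <- divisionRateAt(cfg@divisionRate, xNew)
    dLam <- dt * (Bcur[alive] + Bnew) / 2
    crossed <- Lam[alive] + dLam >= E[alive]
    ia <- which(alive)
    if (any(crossed)) {
      ic <- ia[crossed]
      frac <- (E[ic] - Lam[ic]) / pmax(dLam[crossed], 1e-300)
      age[ic] <- t[ic] + frac * dt
      xd[ic] <- x[ic] + frac * (xNew[crossed] - x[ic])
      alive[ic] <- FALSE
    }
    iu <- ia[!crossed]
    x[iu] <- xNew[!crossed]
    Bcur[iu] <- Bnew[!crossed]
    Lam[iu] <- Lam[iu] + dLam[!crossed]
    t[iu] <- t[iu] + dt
    if (length(iu) && min(t[iu]) > horizon)
      stopf("divergent lifetime: no division within %.0f min", horizon)
  }
  list(age = age, xd = xd)
}

#' Simulate complete cell cycles along lineages
#'
#' Fast path that samples cell cycles directly along `nChannels` independent
#' lines of descent (one daughter followed per division, as in a
#' mother machine) and returns per-cycle summaries without emitting frame
#' rows. The first `burnin` generations are discarded so the retained cycles
#' approximate the stable regime. Same generative law as
#' [simulateMotherMachine()]; cross-checked against the frame-level
#' simulators in the test suite.
#'
#' @param config a [SimConfig].
#' @param n number of cycles to return.
#' @return a `data.frame` of cell cycles (`cell_id, birth_time_min,
#'   birth_size_um, division_time_min, division_size_um, division_age_min,
#'   growth_rate_per_min, septum_ratio, complete` plus `channel`,
#'   `generation`).
#' @export
simulateCycles <- function(config, n) {
  set.seed(config@seed)
  cache <- hazardCache(config)
  L <- min(config@nChannels, n)
  G <- config@burnin + ceiling(n / L)
  xb <- rlnorm(L, config@initialMeanLog, config@initialSdLog)
  tb <- numeric(L)
  frac <- rep(NA_real_, L)
  out <- vector("list", G)
  for (g in seq_len(G)) {
    vi <- drawRates(L, config)
    cyc <- sampleCycleBatch(config, cache, xb, vi)
    theta <- drawSeptum(L, config)
    pickFirst <- runif(L) < 0.5
    keepFrac <- ifelse(pickFirst, theta, 1 - theta)
    if (g > config@burnin)
      out[[g]] <- data.table(
        channel = seq_len(L), generation = g - config@burnin,
        birth_time_min = tb, birth_size_um = xb,
        division_time_min = tb + cyc$age, division_size_um = cyc$xd,
        division_age_min = cyc$age, growth_rate_per_min = vi,
        septum_ratio = frac, complete = TRUE)
    tb <- tb + cyc$age
    frac <- keepFrac
    xb <- keepFrac * cyc$xd
  }
  cycles <- rbindlist(out)[seq_len(n)]
  cycles[, cell_id := .I]
  setDF(cycles)
  cycles[, c("cell_id", "birth_time_min", "birth_size_um", "division_time_min",
             "division_size_um", "division_age_min", "growth_rate_per_min",
             "septum_ratio", "complete", "channel", "generation")]
}

## Emit frame rows for a set of cells. Frames sit on per-cell grids anchored
## at birth: ages 0, dt, ..., (J-1) dt with (J-1) dt strictly below the
## division age (complete cells) or up to the observation end (incomplete).
emitFrames <- function(cells, cfg) {
  dt <- cfg@acquisitionDt
  aObs <- ifelse(cells$complete, cells$division_age,
                 cells$obs_end - cells$birth_time)
  J <- pmax(1L, ifelse(cells$complete,
                       ceiling(cells$division_age / dt - 1e-12),
                       floor((cells$obs_end - cells$birth_time) / dt + 1e-12) + 1L))
  idx <- rep(seq_len(nrow(cells)), J)
  age <- (sequence(J) - 1) * dt
  len <- sizeAfter(cfg@growthLaw, cells$birth_size[idx], age,
                   scale = cells$growth_rate[idx] / cfg@meanRate)
  data.table(cell_id = cells$cell_id[idx],
             parent_id = cells$parent_id[idx],
             time_min = cells$birth_time[idx] + age,
             length_um = len)
}

finishTracks <- function(frames, cells, cfg) {
  setorder(frames, cell_id, time_min)
  setDF(frames)
  attr(frames, "cells") <- cells
  attr(frames, "config") <- cfg
  frames
}

#' Simulate a full genealogical tree of growing, dividing cells
#'
#' Exact event-driven branching simulation under the configured control law:
#' every descendant of the founder cells is kept until `duration`. Lengths
#' are reported at the acquisition interval on per-cell frame grids anchored
#' at birth; a daughter's first frame sits exactly at the division event, so
#' the two daughters' first lengths sum to the mother's division length
#' exactly (pre measurement noise).
#'
#' @param config a [SimConfig] with `topology = "full_tree"`.
#' @return a TrackTable `data.frame` (`cell_id, parent_id, time_min,
#'   length_um`) with the per-cell event table in `attr(, "cells")` and the
#'   configuration in `attr(, "config")`.
#' @seealso [simulateMotherMachine()], [extractCycles()],
#'   [applyMeasurementLayer()]
#' @export
simulatePopulation <- function(config) {
  if (config@topology != "full_tree")
    stopf("simulatePopulation needs topology = 'full_tree'")
  set.seed(config@seed)
  cache <- hazardCache(config)
  nInit <- config@nInitial
  ## founders start at staggered cycle phases (uniform over one doubling
  ## time) so the population desynchronizes quickly, as a real microcolony
  ## seeded from unsynchronized cells would
  batch <- data.table(
    cell_id = seq_len(nInit), parent_id = NA_integer_,
    birth_time = if (nInit > 1L) runif(nInit, 0, log(2) / config@meanRate) else 0,
    birth_size = rlnorm(nInit, config@initialMeanLog, config@initialSdLog),
    septum_ratio = NA_real_)
  nextId <- nInit + 1L
  done <- vector("list", 64L); nd <- 0L
  total <- nInit
  while (nrow(batch) > 0L) {
    vi <- drawRates(nrow(batch), config)
    cyc <- sampleCycleBatch(config, cache, batch$birth_size, vi)
    td <- batch$birth_time + cyc$age
    divides <- td <= config@duration
    theta <- drawSeptum(nrow(batch), config)
    cells <- data.table(
      cell_id = batch$cell_id, parent_id = batch$parent_id,
      birth_time = batch$birth_time, birth_size = batch$birth_size,
      division_time = ifelse(divides, td, NA_real_),
      division_size = ifelse(divides, cyc$xd, NA_real_),
      division_age = ifelse(divides, cyc$age, NA_real_),
      growth_rate = vi, septum_ratio = batch$septum_ratio,
      complete = divides, obs_end = config@duration)
    nd <- nd + 1L
    done[[nd]] <- cells
    ndiv <- sum(divides)
    if (ndiv > 0L) {
      mothers <- which(divides)
      ids <- nextId + seq_len(2L * ndiv) - 1L
      nextId <- nextId + 2L * ndiv
      total <- total + 2L * ndiv
      if (total > config@maxCells) {
        partial <- finishTracks(emitFrames(rbindlist(done), config),
                                rbindlist(done), config)
        stop(errorCondition(
          sprintf("population cap exceeded (%d cells > maxCells = %d)",
                  total, config@maxCells),
          class = c("sizecontrol_population_cap", "error", "condition"),
          partial = partial))
      }
      batch <- data.table(
        cell_id = ids,
        parent_id = rep(batch$cell_id[mothers], each = 2L),
        birth_time = rep(td[mothers], each = 2L),
        birth_size = as.numeric(rbind(theta[mothers] * cyc$xd[mothers],
                                      (1 - theta[mothers]) * cyc$xd[mothers])),
        septum_ratio = as.numeric(rbind(theta[mothers], 1 - theta[mothers])))
    } else {
      batch <- batch[0L]
    }
  }
  cells <- rbindlist(done)
  setorder(cells, cell_id)
  finishTracks(emitFrames(cells, config), cells, config)
}

#' Simulate mother-machine (sparse-tree) lineages
#'
#' Per microchannel a single line of descent is followed for
#' `config@generations` generations; at each division one daughter is
#' retained uniformly at random. The cell present after the last followed
#' division is emitted with its first frame only, so every followed
#' generation has an observed division.
#'
#' @param config a [SimConfig] with `topology = "sparse_tree"`.
#' @return a TrackTable `data.frame`, as [simulatePopulation()].
#' @export
simulateMotherMachine <- function(config) {
  if (config@topology != "sparse_tree")
    stopf("simulateMotherMachine needs topology = 'sparse_tree'")
  set.seed(config@seed)
  cache <- hazardCache(config)
  L <- config@nChannels
  G <- config@generations
  xb <- rlnorm(L, config@initialMeanLog, config@initialSdLog)
  tb <- numeric(L)
  frac <- rep(NA_real_, L)
  parent <- rep(NA_integer_, L)
  gens <- vector("list", G + 1L)
  for (g in seq_len(G)) {
    vi <- drawRates(L, config)
    cyc <- sampleCycleBatch(config, cache, xb, vi)
    theta <- drawSeptum(L, config)
    pickFirst <- runif(L) < 0.5
    keepFrac <- ifelse(pickFirst, theta, 1 - theta)
    ids <- (g - 1L) * L + seq_len(L)
    gens[[g]] <- data.table(
      cell_id = ids, parent_id = parent, birth_time = tb, birth_size = xb,
      division_time = tb + cyc$age, division_size = cyc$xd,
      division_age = cyc$age, growth_rate = vi, septum_ratio = frac,
      complete = TRUE, obs_end = NA_real_, channel = seq_len(L),
      generation = g)
    parent <- ids
    tb <- tb + cyc$age
    frac <- keepFrac
    xb <- keepFrac * cyc$xd
  }
  ## terminal cells: observed at birth only
  vi <- drawRates(L, config)
  gens[[G + 1L]] <- data.table(
    cell_id = G * L + seq_len(L), parent_id = parent, birth_time = tb,
    birth_size = xb, division_time = NA_real_, division_size = NA_real_,
    division_age = NA_real_, growth_rate = vi, septum_ratio = frac,
    complete = FALSE, obs_end = tb, channel = seq_len(L),
    generation = G + 1L)
  cells <- rbindlist(gens)
  setorder(cells, cell_id)
  finishTracks(emitFrames(cells, config), cells, config)
}
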