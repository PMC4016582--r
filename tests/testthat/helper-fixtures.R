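## Shared, lazily built simulation fixtures. Everything is generated in code
## under fixed seeds; heavier objects are cached so several test files can
## reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## Study conditions: steep sizer hazard (division ~4 um), Weibull timer
## hazard (mean division age = doubling time), 8% rate CV, 4% septum CV.
sizerHazard <- function() presetDivisionRate("sizer", rate = 0.0274)
timerHazard <- function() presetDivisionRate("timer", rate = 0.0274, upper = 120)
cappedLaw <- function()
  growthLaw(0.0274, xMin = 2.3, xMax = 5.3,
            capBelow = "constant", capAbove = "constant")

## Mother-machine sizer dataset, 1e4 usable cycles (generations 11-50).
sizerSparseTracks <- function() fixture("sizerSparseTracks", function() {
  simulateMotherMachine(simConfig("sizer", topology = "sparse_tree",
                                  nChannels = 250L, generations = 50L,
                                  acquisitionDt = 1, seed = 21L))
})

timerSparseTracks <- function() fixture("timerSparseTracks", function() {
  simulateMotherMachine(simConfig("timer", divisionRate = timerHazard(),
                                  growthLaw = cappedLaw(),
                                  topology = "sparse_tree", nChannels = 250L,
                                  generations = 50L, acquisitionDt = 1,
                                  seed = 22L))
})

sizerCycles2e4 <- function() fixture("sizerCycles2e4", function() {
  simulateCycles(simConfig("sizer", topology = "sparse_tree",
                           nChannels = 500L, seed = 42L), 20000L)
})

timerCycles2e4 <- function() fixture("timerCycles2e4", function() {
  simulateCycles(simConfig("timer", divisionRate = timerHazard(),
                           growthLaw = cappedLaw(), topology = "sparse_tree",
                           nChannels = 500L, seed = 43L), 20000L)
})

## Agar-pad-like full-tree sizer run (64 staggered founders).
sizerFullTracks <- function() fixture("sizerFullTracks", function() {
  simulatePopulation(simConfig("sizer", topology = "full_tree",
                               duration = 190, nInitial = 64L, seed = 3L))
})

## Same conditions without phenotypic noise: the stochastic counterpart of
## the plain (single-rate, symmetric-division) Size Model.
sizerFullTracksNoiseless <- function() fixture("sizerFullTracksNoiseless", function() {
  simulatePopulation(simConfig("sizer", topology = "full_tree",
                               duration = 190, nInitial = 64L, seed = 3L,
                               rateCV = 0, septumCV = 0))
})

## Model-evaluation reports are expensive; cache the first seed of each.
sizerEvalReport <- function() fixture("sizerEvalReport", function() {
  evaluateModels(sizerSparseTracks(), generationWindow = c(10L, 50L))
})

timerEvalReport <- function() fixture("timerEvalReport", function() {
  evaluateModels(timerSparseTracks(), generationWindow = c(10L, 50L))
})

## Tiny hand-written three-cell tree: a mother (2 -> 4 um) and two equal
## daughters observed for two frames each.
threeCellTracks <- function() {
  data.frame(
    cell_id = c(1L, 1L, 1L, 2L, 2L, 3L, 3L),
    parent_id = c(NA, NA, NA, 1L, 1L, 1L, 1L),
    time_min = c(0, 2, 4, 5, 7, 5, 7),
    length_um = c(2, 2.4, 3.2, 2.0, 2.2, 2.0, 2.2))
}

relL2Central <- function(rate, trueFun, sample, lo = 0.05, hi = 0.95) {
  g <- rateGrid(rate)
  qs <- quantile(sample, c(lo, hi))
  m <- g >= qs[1L] & g <= qs[2L]
  tr <- trueFun(g)
  sqrt(sum((rateValues(rate)[m] - tr[m])^2) / sum(tr[m]^2))
}
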