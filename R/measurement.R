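#' @include cycles.R
NULL

#' Overlay measurement noise on simulated tracks
#'
#' Emulates the two dominant imprecisions of time-lapse segmentation:
#' multiplicative length noise (each reported length times `1 + eps`,
#' `eps ~ N(0, lengthNoiseCV)` truncated at 3 sigma) and division-time
#' mis-detection (each division event shifted by a Gaussian with SD
#' `divisionTimeNoiseCV` times the mean cycle duration, snapped to the
#' acquisition grid). A late-detected division keeps the mother's row for
#' the extra frames, its length continuing the mother's growth curve (the
#' attached daughters' summed length); an early-detected one reports the
#' daughters prematurely, each with its septum fraction of the mother's
#' length. Genealogy is preserved; event shifts that would leave a cycle
#' without frames are redrawn, and if more than 1% of cycles would be
#' non-positive the configured noise is refused.
#'
#' @param tracks a noiseless TrackTable from [simulatePopulation()] or
#'   [simulateMotherMachine()] (the simulation event table in
#'   `attr(tracks, "cells")` is required).
#' @param config a [SimConfig] supplying `lengthNoiseCV`,
#'   `divisionTimeNoiseCV` and the growth law; the RNG is seeded from
#'   `config@seed` (offset so it does not replay the simulation stream).
#' @return a TrackTable `data.frame`; `attr(, "cells")` gains
#'   `obs_division_time_min` with the perturbed event times.
#' @export
applyMeasurementLayer <- function(tracks, config) {
  cells <- attr(tracks, "cells")
  if (is.null(cells))
    stopf("tracks carry no simulation event table (attr 'cells'); apply the measurement layer to simulator output")
  cells <- as.data.table(cells)
  dtA <- config@acquisitionDt
  law <- config@growthLaw
  set.seed(config@seed + 1L)

  comp <- which(cells$complete)
  k <- integer(nrow(cells))
  if (config@divisionTimeNoiseCV > 0 && length(comp)) {
    meanCycle <- mean(cells$division_age[comp])
    sdNoise <- config@divisionTimeNoiseCV * meanCycle
    J <- pmax(1L, ceiling(cells$division_age / dtA - 1e-12))
    delta <- rnorm(length(comp), 0, sdNoise)
    k[comp] <- as.integer(round(delta / dtA))
    ## a complete cycle must retain >= 1 frame, and an early-detected
    ## division may not precede the mother's own first frame; incomplete
    ## terminal stubs whose frames vanish are silently dropped
    violated <- function(k) {
      kp <- k[match(cells$parent_id, cells$cell_id)]
      kp[is.na(kp)] <- 0L
      cells$complete & (J + k - kp < 1L | J + k < 1L)
    }
    bad <- violated(k)
    if (mean(bad[cells$complete]) > 0.01)
      stopf("division-time noise too large: %.1f%% of cycles would be non-positive",
            100 * mean(bad))
    tries <- 0L
    while (any(bad) && tries < 100L) {
      ## redraw the events implicated in a violation (own or parent's)
      culprit <- unique(c(cells$cell_id[bad & cells$complete],
                          cells$parent_id[bad & !is.na(cells$parent_id)]))
      ridx <- which(cells$cell_id %in% culprit & cells$complete)
      k[ridx] <- as.integer(round(rnorm(length(ridx), 0, sdNoise) / dtA))
      bad <- violated(k)
      tries <- tries + 1L
    }
    if (any(bad))
      stopf("division-time noise too large: could not keep all cycles positive")
  }

  kp <- k[match(cells$parent_id, cells$cell_id)]
  kp[is.na(kp)] <- 0L
  J <- pmax(1L, ceiling(cells$division_age / dtA - 1e-12))
  jStart <- kp
  jEnd <- ifelse(cells$complete, J + k - 1L, frameCount(cells, dtA) - 1L)
  nJ <- pmax(jEnd - jStart + 1L, 0L)  # vanished incomplete stubs drop out
  idx <- rep(seq_len(nrow(cells)), nJ)
  age <- (sequence(nJ) - 1L + jStart[idx]) * dtA
  scale <- cells$growth_rate[idx] / config@meanRate
  len <- numeric(length(idx))
  fwd <- age >= 0
  len[fwd] <- sizeAfter(law, cells$birth_size[idx][fwd], age[fwd], scale[fwd])
  if (any(!fwd)) {
    ## premature split: report the septum fraction of the mother's length
    pi2 <- match(cells$parent_id[idx[!fwd]], cells$cell_id)
    pAge <- pmax(cells$birth_time[idx[!fwd]] + age[!fwd] - cells$birth_time[pi2], 0)
    pLen <- sizeAfter(law, cells$birth_size[pi2], pAge,
                      cells$growth_rate[pi2] / config@meanRate)
    len[!fwd] <- cells$septum_ratio[idx[!fwd]] * pLen
  }
  if (config@lengthNoiseCV > 0) {
    cv <- config@lengthNoiseCV
    len <- len * (1 + rtruncnorm(length(len), 0, cv, -3 * cv, 3 * cv))
  }
  out <- data.table(cell_id = cells$cell_id[idx],
                    parent_id = cells$parent_id[idx],
                    time_min = cells$birth_time[idx] + age,
                    length_um = len)
  cells[, obs_division_time_min := ifelse(complete, division_time + k * dtA,
                                          NA_real_)]
  finishTracks(out, cells, config)
}

## Frames an incomplete cell had in the noiseless emission.
frameCount <- function(cells, dtA) {
  n <- ifelse(cells$complete, pmax(1L, ceiling(cells$division_age / dtA - 1e-12)),
              floor((cells$obs_end - cells$birth_time) / dtA + 1e-12) + 1L)
  as.integer(pmax(1, n, na.rm = FALSE))
}
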