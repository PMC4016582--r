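#' @include simulate.R
NULL

## Assign generations: founders are generation 1, children one more than
## their parent. Level-synchronous propagation over the genealogy.
assignGenerations <- function(cellId, parentId) {
  gen <- ifelse(is.na(parentId), 1L, NA_integer_)
  pidx <- match(parentId, cellId)
  while (anyNA(gen)) {
    newGen <- ifelse(is.na(parentId), 1L, gen[pidx] + 1L)
    if (identical(newGen, gen)) break  # dangling parents: leave NA
    gen <- newGen
  }
  gen
}

#' Extract per-cell cycle summaries from a track table
#'
#' Summarizes each tracked cell into one cycle row: birth size is the first
#' observed length, division size the last observed length, and the division
#' time is the first observation time of the cell's daughters (the daughters'
#' first frames sit at the division event). Cells with no observed division
#' are flagged `complete = FALSE` and are excluded from downstream rate
#' estimation. The per-cell exponential growth rate is fitted by least
#' squares on log-length (cells with fewer than 3 frames get `NA`).
#'
#' The septum ratio of a daughter is its first observed length divided by the
#' mother's division length; when both daughters are observed (full trees)
#' the division length is taken as the sum of the daughters' first lengths,
#' so the two ratios sum to one exactly on noiseless data. With a single
#' observed daughter (sparse trees) the mother's last observed length is
#' used instead.
#'
#' @param tracks a TrackTable `data.frame` (`cell_id, parent_id, time_min,
#'   length_um`).
#' @param discardBefore drop cycles born before this time (min); the
#'   reference full-tree analyses discard the first 150 min of growth.
#' @param generationWindow `c(lo, hi)`: keep generations `lo + 1 .. hi`
#'   (mother-machine analyses keep generations 11-50).
#' @return a `data.frame` of cycles (`cell_id, birth_time_min, birth_size_um,
#'   division_time_min, division_size_um, division_age_min,
#'   growth_rate_per_min, septum_ratio, complete, generation`).
#' @export
extractCycles <- function(tracks, discardBefore = 0, generationWindow = NULL) {
  dt <- as.data.table(tracks)
  requireCols(dt, c("cell_id", "parent_id", "time_min", "length_um"), "tracks")
  setorder(dt, cell_id, time_min)
  per <- dt[, .(
    parent_id = parent_id[1L],
    birth_time_min = time_min[1L],
    birth_size_um = length_um[1L],
    last_time_min = time_min[.N],
    last_length_um = length_um[.N],
    n_frames = .N,
    growth_rate_per_min = {
      if (.N >= 3L && all(length_um > 0)) {
        tt <- time_min - time_min[1L]
        ll <- log(length_um)
        sum((tt - mean(tt)) * (ll - mean(ll))) / sum((tt - mean(tt))^2)
      } else NA_real_
    }), by = cell_id]
  ## division events seen from the daughters
  kids <- per[!is.na(parent_id),
              .(division_time_min = birth_time_min[1L],
                kid_sum = sum(birth_size_um), n_kids = .N),
              by = parent_id]
  per <- merge(per, kids, by.x = "cell_id", by.y = "parent_id", all.x = TRUE)
  per[, complete := !is.na(division_time_min)]
  per[, division_size_um := ifelse(complete, last_length_um, NA_real_)]
  per[, division_age_min := division_time_min - birth_time_min]
  ## septum ratio of each daughter
  pidx <- match(per$parent_id, per$cell_id)
  motherDiv <- ifelse(!is.na(pidx) & !is.na(per$n_kids[pidx]) & per$n_kids[pidx] >= 2L,
                      per$kid_sum[pidx], per$last_length_um[pidx])
  per[, septum_ratio := birth_size_um / motherDiv]
  per[, generation := assignGenerations(cell_id, parent_id)]
  keep <- per$birth_time_min >= discardBefore
  if (!is.null(generationWindow)) {
    if (length(generationWindow) != 2L || generationWindow[1L] >= generationWindow[2L])
      stopf("generationWindow must be c(lo, hi) with lo < hi")
    keep <- keep & !is.na(per$generation) &
      per$generation > generationWindow[1L] & per$generation <= generationWindow[2L]
  }
  per <- per[keep]
  if (!any(per$complete))
    stopf("no usable cycles: no complete cycle after filtering")
  out <- per[, .(cell_id, birth_time_min, birth_size_um, division_time_min,
                 division_size_um, division_age_min, growth_rate_per_min,
                 septum_ratio, complete, generation)]
  setDF(out)
  out
}

requireCols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
}

#' Validate a track table
#'
#' Checks the TrackTable contract: required columns, positive lengths,
#' strictly increasing constant-spaced times within each cell, and a
#' consistent genealogy (every non-root `parent_id` exists and the parent's
#' last frame precedes the child's first). Errors carry row numbers and cell
#' identifiers.
#'
#' @param tracks a TrackTable `data.frame`.
#' @return `tracks`, invisibly, when valid.
#' @export
validateTracks <- function(tracks) {
  dt <- as.data.table(tracks)
  requireCols(dt, c("cell_id", "parent_id", "time_min", "length_um"), "tracks")
  bad <- which(!is.finite(dt$length_um) | dt$length_um <= 0)
  if (length(bad))
    stopf("non-positive length at row(s) %s", paste(head(bad, 5L), collapse = ", "))
  dt[, row__ := .I]
  chk <- dt[, {
    ts <- time_min[order(time_min)]
    ok <- .N < 2L || (all(diff(ts) > 0) &&
                      (diff(range(diff(ts))) < 1e-8 * max(diff(ts), 1)))
    .(ok = ok, row1 = row__[1L])
  }, by = cell_id]
  if (any(!chk$ok))
    stopf("non-monotone or unevenly spaced times for cell(s) %s (first at row %d)",
          paste(head(chk$cell_id[!chk$ok], 5L), collapse = ", "),
          chk$row1[which(!chk$ok)[1L]])
  per <- dt[, .(first = min(time_min), last = max(time_min)), by = cell_id]
  pidx <- match(dt$parent_id, per$cell_id)
  dangling <- !is.na(dt$parent_id) & is.na(pidx)
  if (any(dangling))
    stopf("dangling parent_id '%s' at row %d",
          dt$parent_id[which(dangling)[1L]], which(dangling)[1L])
  firstFrame <- dt[, .(first = min(time_min)), by = .(cell_id, parent_id)]
  pLast <- per$last[match(firstFrame$parent_id, per$cell_id)]
  late <- !is.na(firstFrame$parent_id) & !is.na(pLast) & firstFrame$first <= pLast
  if (any(late)) {
    i <- which(late)[1L]
    stopf("cell %s starts at %.6g, not after the last frame (%.6g) of its parent %s",
          firstFrame$cell_id[i], firstFrame$first[i], pLast[i],
          firstFrame$parent_id[i])
  }
  invisible(tracks)
}
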