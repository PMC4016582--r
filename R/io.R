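#' @include cycles.R
NULL

#' Read and write track tables
#'
#' TrackTable CSV dialect: header `cell_id,parent_id,time_min,length_um`,
#' empty `parent_id` for founder cells, `.` decimal separator, UTF-8. Extra
#' columns (e.g. a width column) are preserved. Reading validates the table
#' ([validateTracks()]) with row-numbered diagnostics.
#'
#' @param path file path.
#' @return `readTracks`: a validated TrackTable `data.frame`.
#' @export
readTracks <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- fread(path, sep = ",", na.strings = "")
  requireCols(dt, c("cell_id", "parent_id", "time_min", "length_um"), basename(path))
  setDF(dt)
  validateTracks(dt)
  dt
}

#' @rdname readTracks
#' @param tracks a TrackTable `data.frame`.
#' @return `writeTracks`: `path`, invisibly.
#' @export
writeTracks <- function(tracks, path) {
  fwrite(as.data.table(tracks), path, sep = ",", na = "", quote = FALSE)
  invisible(path)
}

#' Read and write cycle tables
#'
#' CellCycle CSV dialect: `cell_id,birth_time_min,birth_size_um,
#' division_time_min,division_size_um,division_age_min,growth_rate_per_min,
#' septum_ratio,complete` (extra columns preserved).
#'
#' @param path file path.
#' @return `readCycles`: a cycle `data.frame`.
#' @export
readCycles <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- fread(path, sep = ",", na.strings = "")
  requireCols(dt, c("cell_id", "birth_time_min", "birth_size_um",
                    "division_age_min", "complete"), basename(path))
  setDF(dt)
  dt
}

#' @rdname readCycles
#' @param cycles a cycle `data.frame`.
#' @export
writeCycles <- function(cycles, path) {
  fwrite(as.data.table(cycles), path, sep = ",", na = "", quote = FALSE)
  invisible(path)
}

#' Read and write tabulated division rates
#'
#' CSV dialect: `grid_value,rate_per_min,reliable` plus a comment header
#' line recording the index (`age`/`size`) and extrapolation rule.
#'
#' @param path file path.
#' @return `readDivisionRate`: a [DivisionRate].
#' @export
readDivisionRate <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# index=")) stopf("missing index header in %s", path)
  meta <- strsplit(sub("^# ", "", first), " ")[[1L]]
  kv <- do.call(rbind, strsplit(meta, "="))
  idx <- kv[kv[, 1L] == "index", 2L]
  ext <- kv[kv[, 1L] == "extrapolation", 2L]
  dt <- fread(path, sep = ",", skip = 1L)
  divisionRate(idx, dt$grid_value, dt$rate_per_min,
               reliable = as.logical(dt$reliable), extrapolation = ext)
}

#' @rdname readDivisionRate
#' @param rate a [DivisionRate].
#' @export
writeDivisionRate <- function(rate, path) {
  writeLines(sprintf("# index=%s extrapolation=%s", rate@index,
                     rate@extrapolation), path)
  fwrite(data.table(grid_value = rate@grid, rate_per_min = rate@values,
                    reliable = rate@reliable),
         path, sep = ",", append = TRUE, col.names = TRUE)
  invisible(path)
}
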