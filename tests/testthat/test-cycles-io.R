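test_that("a three-cell tree yields one complete mother and two stubs", {
  cyc <- extractCycles(threeCellTracks())
  mother <- cyc[cyc$cell_id == 1L, ]
  expect_true(mother$complete)
  expect_equal(mother$division_time_min, 5)     # daughters' first frame
  expect_equal(mother$division_age_min, 5)
  expect_equal(mother$division_size_um, 3.2)    # last observed length
  kids <- cyc[cyc$cell_id %in% c(2L, 3L), ]
  expect_false(any(kids$complete))
  expect_equal(kids$septum_ratio, c(0.5, 0.5))  # 2.0 / (2.0 + 2.0)
  expect_true(all(is.na(kids$growth_rate_per_min)))  # < 3 frames
})

test_that("time and generation filters behave as documented", {
  tr <- sizerFullTracks()
  cyc <- extractCycles(tr, discardBefore = 150)
  expect_true(all(cyc$division_time_min[cyc$complete] >= 150))
  mm <- sizerSparseTracks()
  cycG <- extractCycles(mm, generationWindow = c(10L, 50L))
  expect_true(all(cycG$generation > 10L & cycG$generation <= 50L))
  expect_equal(sum(cycG$complete), 250L * 40L)
  expect_error(extractCycles(tr, discardBefore = 1e6), "no usable cycles")
})

test_that("track round-trips preserve the table and extra columns", {
  tr <- head(simulateMotherMachine(simConfig("sizer", topology = "sparse_tree",
                                             nChannels = 5L, generations = 4L,
                                             seed = 2L)), 200L)
  path <- tempfile(fileext = ".csv")
  writeTracks(tr, path)
  back <- readTracks(path)
  expect_equal(back$cell_id, tr$cell_id)
  expect_equal(back$length_um, tr$length_um, tolerance = 1e-12)
  ## tolerant dialect: extra width column survives
  tr$width_um <- 0.9
  writeTracks(tr, path)
  expect_true("width_um" %in% names(readTracks(path)))
})

test_that("validation errors name the offending rows and cells", {
  bad <- threeCellTracks()
  bad$parent_id[4:7] <- 99L
  expect_error(validateTracks(bad), "dangling parent_id")
  early <- threeCellTracks()
  early$time_min[4] <- 3   # child frame before parent's last frame
  expect_error(validateTracks(early), "not after the last frame")
  neg <- threeCellTracks()
  neg$length_um[2] <- -1
  expect_error(validateTracks(neg), "row")
  uneven <- threeCellTracks()
  uneven$time_min[3] <- 3.7
  expect_error(validateTracks(uneven), "unevenly spaced")
  expect_error(readTracks(tempfile()), "no such file")
})

test_that("cycle and division-rate files round-trip", {
  cyc <- head(sizerCycles2e4(), 50L)
  path <- tempfile(fileext = ".csv")
  writeCycles(cyc, path)
  back <- readCycles(path)
  expect_equal(back$division_age_min, cyc$division_age_min, tolerance = 1e-10)
  B <- presetDivisionRate("sizer")
  pB <- tempfile(fileext = ".csv")
  writeDivisionRate(B, pB)
  B2 <- readDivisionRate(pB)
  expect_equal(rateIndex(B2), "size")
  expect_equal(rateValues(B2), rateValues(B), tolerance = 1e-8)
})
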