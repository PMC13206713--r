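test_that("write -> read round trip is lossless", {
  gv <- generate_volume(small_scene(noise_sd = 20, seed = 9, n_ascans = 64),
                        n_bscans = 4)
  path <- tempfile(fileext = ".tiff")
  write_volume(gv$volume, path)
  v2 <- read_volume(path)
  expect_identical(lapply(gv$volume$images, unname),
                   lapply(v2$images, unname))
  expect_identical(unname(gv$volume$rpe_curve), unname(v2$rpe_curve))
  expect_identical(unname(gv$volume$csj_curve), unname(v2$csj_curve))
  expect_identical(gv$volume$quality_db, v2$quality_db)
  expect_identical(gv$volume$fovea_xy_um, v2$fovea_xy_um)
  expect_identical(gv$volume$ascan_spacing_um, v2$ascan_spacing_um)
  expect_identical(gv$volume$bscan_spacing_um, v2$bscan_spacing_um)
  expect_identical(gv$volume$laterality, v2$laterality)
})

test_that("inconsistent sidecar and missing boundaries raise format errors", {
  gv <- generate_volume(small_scene(n_ascans = 32, noise_sd = 0), n_bscans = 3)
  path <- tempfile(fileext = ".tiff")
  write_volume(gv$volume, path)
  side <- sub("\\.tiff$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)

  meta_bad <- meta
  meta_bad$n_bscans <- 4
  jsonlite::write_json(meta_bad, side, digits = I(17), auto_unbox = TRUE)
  expect_error(read_volume(path), "n_bscans")

  meta_bad <- meta
  meta_bad$csj_curve <- NULL
  jsonlite::write_json(meta_bad, side, digits = I(17), auto_unbox = TRUE)
  expect_error(read_volume(path), "required inputs")

  expect_error(read_volume(tempfile(fileext = ".tiff")), "not found")
})

test_that("volume constructor validates boundary ordering", {
  img <- list(matrix(0, 10, 4))
  rpe <- matrix(5, 1, 4)
  csj <- matrix(4, 1, 4)
  expect_error(
    oct_volume(img, 10, 0, 3.9, 20, "OD", c(20, 0), rpe, csj),
    "csj_curve < rpe_curve")
})

test_that("QC keeps good volumes and rejects three or more poor B-scans", {
  gv <- generate_volume(clean_scene(n_ascans = 16, quality_db = 20))
  qc <- qc_filter(gv$volume)
  expect_true(qc$volume_accepted)
  expect_length(qc$excluded_bscans, 0)

  # three scans at 14 dB among 61: participant excluded
  v <- gv$volume
  v$quality_db[c(5, 20, 40)] <- 14
  qc3 <- qc_filter(v)
  expect_false(qc3$volume_accepted)
  expect_equal(qc3$excluded_bscans, c(5, 20, 40))

  # exactly two below threshold: accepted with the exclusions recorded
  v$quality_db <- rep(20, 61)
  v$quality_db[c(2, 3)] <- 14.9
  qc2 <- qc_filter(v)
  expect_true(qc2$volume_accepted)
  expect_length(qc2$excluded_bscans, 2)

  # the threshold is strict: exactly 15.0 dB passes
  v$quality_db <- rep(15, 61)
  expect_true(qc_filter(v)$volume_accepted)
  expect_length(qc_filter(v)$excluded_bscans, 0)
})

test_that("QC-excluded scans invalidate their grid rows rather than zeroing", {
  sc <- clean_scene(seed = 4)
  gv <- generate_volume(sc, n_bscans = 8)
  v <- gv$volume
  v$quality_db[3] <- 10
  grid <- quantify_volume(v, detect_shadows = FALSE)
  y <- (3 - 1) * v$bscan_spacing_um - v$fovea_xy_um[["y"]]
  row_bad <- grid_index(0, y)$row + 1L
  expect_false(any(grid$valid_mask[row_bad, ]))
  expect_true(all(is.na(grid$cvi[row_bad, ])))
})
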