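test_that("shadow detection flags all shadowed columns with few false alarms", {
  sc <- small_scene(noise_sd = 20, n_shadow_columns = 3, n_ascans = 256,
                    seed = 5)
  b <- generate_bscan(sc, 30)
  valid <- detect_shadow_columns(b$image, b$truth$rpe_curve)
  shadow <- b$truth$shadow_columns
  expect_true(all(!valid[shadow]))
  # false positives outside the prescribed +/-1 dilation margin of true bands
  margin <- unique(pmin(pmax(c(shadow - 1L, shadow, shadow + 1L), 1L), 256L))
  clean <- setdiff(seq_along(valid), shadow)
  fp <- sum(!valid[setdiff(clean, margin)])
  expect_lte(fp / length(clean), 0.02)
})

test_that("clean noiseless scans flag no columns; identity attenuation is a no-op", {
  b0 <- generate_bscan(clean_scene(n_ascans = 256, seed = 5), 30)
  expect_true(all(detect_shadow_columns(b0$image, b0$truth$rpe_curve)))
  b1 <- generate_bscan(small_scene(noise_sd = 0, n_shadow_columns = 3,
                                   shadow_attenuation = 1, n_ascans = 256,
                                   seed = 5), 30)
  expect_true(all(detect_shadow_columns(b1$image, b1$truth$rpe_curve)))
})

test_that("noiseless bimodal binarization matches truth exactly", {
  b <- generate_bscan(clean_scene(seed = 7), 0, n_bscans = 1)
  mask <- binarize_choroid(b$image, b$truth$rpe_curve, b$truth$csj_curve)
  expect_identical(mask, b$truth$lumen_mask)
})

test_that("binarization under noise agrees with truth on >= 95% of pixels", {
  b <- generate_bscan(small_scene(noise_sd = 20, seed = 11, n_ascans = 256),
                      0, n_bscans = 1)
  mask <- binarize_choroid(b$image, b$truth$rpe_curve, b$truth$csj_curve)
  band <- b$truth$band_mask
  agreement <- mean(mask[band] == b$truth$lumen_mask[band])
  expect_gte(agreement, 0.95)
})

test_that("constant-intensity band labels everything stroma with a warning", {
  img <- matrix(128, 100, 40)
  rpe <- rep(20, 40)
  csj <- rep(60, 40)
  expect_warning(mask <- binarize_choroid(img, rpe, csj), "constant")
  expect_equal(sum(mask), 0)
  expect_error(binarize_choroid(img, rep(90, 40), rep(90, 40)), "empty")
})

test_that("binarization parameters are validated", {
  expect_error(binarization_params(n_levels = 3), "power of two")
  expect_error(binarization_params(window_widths_px = -4), "positive")
  expect_s3_class(binarization_params(n_levels = 8), "binarization_params")
})

test_that("column metrics compute CT from real-valued boundaries", {
  img <- matrix(100, 200, 3)
  lum <- matrix(FALSE, 200, 3)
  cm <- compute_column_metrics(img, rpe_curve = rep(100, 3),
                               csj_curve = rep(180, 3), lumen_mask = lum,
                               axial_res_um = 3.9)
  expect_equal(cm$ct_um, rep(80 * 3.9, 3))   # 312 um
  expect_equal(cm$lumen_px + cm$stroma_px, rep(80, 3))

  # empty band: zero thickness, zero counts
  cm0 <- compute_column_metrics(img, rep(100, 3), rep(100, 3), lum)
  expect_equal(cm0$ct_um, rep(0, 3))
  expect_equal(cm0$lumen_px, rep(0, 3))
  expect_equal(cm0$stroma_px, rep(0, 3))

  # inverted boundaries invalidate the column with a reason code
  cmi <- compute_column_metrics(img, c(100, 100, 100), c(180, 90, 180), lum)
  expect_false(cmi$valid[2])
  expect_equal(cmi$reason[2], "inverted_boundaries")
  expect_true(all(cmi$valid[c(1, 3)]))
})

test_that("an all-lumen band aggregates to CVI 1", {
  img <- matrix(60, 200, 3)
  band_lum <- choromap:::band_mask(200, rep(100, 3), rep(180, 3))
  cm <- compute_column_metrics(img, rep(100, 3), rep(180, 3), band_lum)
  expect_equal(sum(cm$lumen_px) / sum(cm$lumen_px + cm$stroma_px), 1)
})

test_that("grid aggregation yields 3600 cells with exact conservation", {
  gv <- generate_volume(clean_scene(seed = 3), n_bscans = 10)
  grid <- quantify_volume(gv$volume, detect_shadows = FALSE)
  for (f in c("ct_um", "la_um2", "sa_um2", "cvi")) {
    expect_equal(dim(grid[[f]]), c(60, 60))
  }
  ok <- grid$valid_mask
  px_area <- gv$volume$ascan_spacing_um * gv$volume$axial_res_um
  band_px <- (grid$la_um2[ok] + grid$sa_um2[ok]) / px_area
  expect_true(all(abs(band_px - round(band_px)) < 1e-9))
  expect_true(all(grid$cvi[ok] >= 0 & grid$cvi[ok] <= 1))
  expect_true(all(is.na(grid$cvi[!ok])))
})

test_that("pipeline CVI equals truth exactly on noiseless volumes", {
  gv <- generate_volume(clean_scene(seed = 13), n_bscans = 10)
  grid <- quantify_volume(gv$volume, detect_shadows = FALSE)
  tr <- gv$truth$cell_truth
  ok <- grid$valid_mask & !is.na(tr$cvi)
  expect_gt(sum(ok), 500)
  expect_lte(max(abs(grid$cvi[ok] - tr$cvi[ok])), 1e-6)
  expect_lte(max(abs(grid$ct_um[ok] - tr$ct_um[ok])), 1e-9)
  # homogeneous 0.65 target: every valid cell in [0.64, 0.66]
  expect_true(all(grid$cvi[ok] >= 0.64 & grid$cvi[ok] <= 0.66))
})

test_that("a single-B-scan volume populates exactly one grid row band", {
  gv <- generate_volume(clean_scene(seed = 2), n_bscans = 1)
  grid <- quantify_volume(gv$volume, detect_shadows = FALSE)
  rows_used <- which(apply(grid$valid_mask, 1, any))
  expect_equal(rows_used, 31)  # fovea row: grid_index(0, 0) = (30, 30) 0-based
  expect_true(all(is.na(grid$cvi[-31, ])))
})

test_that("median grid CVI is nondecreasing in the target lumen fraction", {
  meds <- vapply(c(0.40, 0.55, 0.70), function(f) {
    gv <- generate_volume(small_scene(lumen_fraction = f, noise_sd = 20,
                                      seed = 2), n_bscans = 6)
    g <- quantify_volume(gv$volume, detect_shadows = FALSE)
    median(g$cvi[g$valid_mask])
  }, 0)
  expect_true(all(diff(meds) >= 0))
})

test_that("an off-centre fovea triggers the coverage warning", {
  gv <- generate_volume(clean_scene(n_ascans = 64, seed = 6), n_bscans = 4)
  v <- gv$volume
  v$fovea_xy_um["x"] <- v$fovea_xy_um[["x"]] + 3000
  cm <- lapply(seq_along(v$images), function(s) {
    compute_column_metrics(v$images[[s]], v$rpe_curve[s, ], v$csj_curve[s, ],
                           matrix(FALSE, nrow(v$images[[s]]), ncol(v$images[[s]])))
  })
  expect_warning(aggregate_to_grid(cm, v), "outside the scanned area")
})
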