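test_that("B-scan geometry follows the acquisition protocol", {
  b <- generate_bscan(clean_scene(), 0, n_bscans = 3)
  expect_equal(nrow(b$image), round(1800 / 3.9))
  expect_equal(ncol(b$image), 128)
  # choroid band lies between the boundary curves
  band <- b$truth$band_mask
  for (j in c(1, 64, 128)) {
    rows <- which(band[, j])
    expect_true(all(rows > floor(b$truth$rpe_curve[j])))
    expect_true(all(rows <= floor(b$truth$csj_curve[j])))
  }
})

test_that("noiseless choroid band is exactly bimodal", {
  b <- generate_bscan(clean_scene(stroma_intensity = 180, lumen_intensity = 60),
                      0, n_bscans = 1)
  expect_setequal(unique(as.vector(b$image[b$truth$band_mask])), c(60, 180))
  # lumen pixels carry the lumen intensity exactly
  expect_true(all(b$image[b$truth$lumen_mask] == 60))
})

test_that("zero lumen fraction yields no lumen pixels and zero truth CVI", {
  gv <- generate_volume(clean_scene(lumen_fraction = 0), n_bscans = 4)
  expect_equal(sum(vapply(gv$truth$lumen_stack, sum, 0)), 0)
  cvi <- gv$truth$cell_truth$cvi
  expect_true(all(cvi[!is.na(cvi)] == 0))
})

test_that("realized lumen fraction is within tolerance of the target", {
  b <- generate_bscan(clean_scene(lumen_fraction = 0.65, seed = 7), 0,
                      n_bscans = 1)
  f <- sum(b$truth$lumen_mask) / sum(b$truth$band_mask)
  expect_gte(f, 0.64)
  expect_lte(f, 0.66)
})

test_that("tissue labels partition every pixel", {
  b <- generate_bscan(small_scene(noise_sd = 20, n_shadow_columns = 2), 0,
                      n_bscans = 1)
  expect_true(all(b$truth$labels %in% 1:5))
  expect_equal(length(b$truth$labels), length(b$image))
  # shadow columns relabelled below the inner retinal surface
  expect_true(all(b$truth$labels[, b$truth$shadow_columns][400, ] == 2))
})

test_that("same seed reproduces a volume bit for bit; B-scans match slices", {
  a <- generate_volume(small_scene(noise_sd = 20, seed = 5), n_bscans = 3)
  b <- generate_volume(small_scene(noise_sd = 20, seed = 5), n_bscans = 3)
  expect_identical(a, b)
  bs <- generate_bscan(small_scene(noise_sd = 20, seed = 5), 1, n_bscans = 3)
  expect_identical(bs$image, a$volume$images[[2]])
})

test_that("default protocol yields 61 B-scans spanning 7200 um", {
  sc <- clean_scene(n_ascans = 16)
  gv <- generate_volume(sc)
  expect_length(gv$volume$images, 61)
  expect_equal(gv$volume$bscan_spacing_um, 7200 / 60)
  expect_equal(gv$volume$axial_res_um, 3.9)
})

test_that("truth cell areas satisfy exact conservation", {
  gv <- generate_volume(clean_scene(seed = 3), n_bscans = 6)
  ct <- gv$truth$cell_truth
  px_area <- gv$volume$ascan_spacing_um * gv$volume$axial_res_um
  ok <- ct$sampled
  # LA + SA equals the cell's choroid pixel count times the pixel area
  band_px <- (ct$la_um2[ok] + ct$sa_um2[ok]) / px_area
  expect_true(all(abs(band_px - round(band_px)) < 1e-9))
  # CVI = LA / (LA + SA) exactly
  expect_equal(ct$cvi[ok], ct$la_um2[ok] / (ct$la_um2[ok] + ct$sa_um2[ok]))
})

test_that("invalid scene parameters are rejected", {
  expect_error(scene_params(lumen_intensity = 200, stroma_intensity = 180),
               "lumen_intensity")
  expect_error(scene_params(lumen_fraction = 1.2), "lumen_fraction")
  expect_error(
    generate_bscan(clean_scene(lumen_fraction = 0.1,
                               vessel_axes_um = c(300, 400)), 0, n_bscans = 1),
    "unreachable")
})

test_that("cohort embedding is exact without noise and respects bounds", {
  coh <- quick_cohort(c(1.16, -1.79), n = 3, eye_sd = 0, cell_sd = 0)
  dm <- difference_map(coh$iamd, coh$control, "cvi")
  expect_equal(dm$values[dm$valid_mask],
               coh$truth$true_change$cvi[dm$valid_mask], tolerance = 1e-12)
  # null effect with no noise: groups identical, map exactly zero
  coh0 <- quick_cohort(NULL, n = 3, eye_sd = 0, cell_sd = 0)
  dm0 <- difference_map(coh0$iamd, coh0$control, "cvi")
  expect_true(all(dm0$values[dm0$valid_mask] == 0))
  # profiles reaching +/-200% are rejected
  expect_error(quick_cohort(c(0, 250), n = 2), "within")
})

test_that("cohorts are reproducible under a fixed seed", {
  a <- quick_cohort(c(4, -20, 16), n = 3, seed = 9)
  b <- quick_cohort(c(4, -20, 16), n = 3, seed = 9)
  expect_identical(a, b)
})
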