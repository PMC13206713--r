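test_that("percent-change formulas match hand-computed values", {
  expect_equal(symmetric_percent_change(100, 100), 0)
  expect_equal(symmetric_percent_change(90, 110), -20)
  expect_equal(symmetric_percent_change(90, 110, mode = "raw"), -100 * 20 / 90)
  expect_equal(symmetric_percent_change(1, 0), 200)  # supremum of the formula
})

test_that("symmetric percent change is antisymmetric and bounded", {
  set.seed(1)
  a <- runif(500, 0.01, 1000)
  b <- runif(500, 0.01, 1000)
  expect_equal(symmetric_percent_change(a, b),
               -symmetric_percent_change(b, a))
  expect_true(all(abs(symmetric_percent_change(a, b)) < 200))
  # raw mode is unbounded below as the denominator shrinks
  expect_lt(symmetric_percent_change(0.001, 10, mode = "raw"), -200)
})

test_that("difference maps of identical cohorts are zero and antisymmetric", {
  coh <- quick_cohort(c(4, -20, 16), n = 4, seed = 2)
  dm_same <- difference_map(coh$control, coh$control, "cvi")
  expect_true(all(dm_same$values[dm_same$valid_mask] == 0))
  ab <- difference_map(coh$iamd, coh$control, "cvi")
  ba <- difference_map(coh$control, coh$iamd, "cvi")
  expect_equal(ab$values, -ba$values)
  expect_error(difference_map(coh$iamd[1], coh$control, "cvi"), "2 eyes")
})

test_that("an embedded profile is tracked by the annulus medians", {
  coh <- quick_cohort(c(4, -20, 16), n = 40, eye_sd = 3, cell_sd = 6,
                      seed = 11)
  dm <- difference_map(coh$iamd, coh$control, "cvi")
  cc <- grid_cell_centers()
  bins <- eccentricity_bin(cc$r_mm[dm$valid_mask])
  med <- tapply(dm$values[dm$valid_mask], bins, median)
  truth <- tapply(coh$truth$true_change$cvi[dm$valid_mask], bins, median)
  keep <- as.numeric(names(med)) <= 60
  expect_lte(max(abs(med[keep] - truth[keep])), 2)  # percent points
})

test_that("fully invalid input produces a fully invalid map", {
  coh <- quick_cohort(NULL, n = 2, eye_sd = 0, cell_sd = 0)
  broken <- lapply(coh$iamd, function(g) {
    g$valid_mask[] <- FALSE
    g
  })
  expect_warning(dm <- difference_map(broken, coh$control, "cvi"),
                 "no valid cells")
  expect_false(any(dm$valid_mask))
})

test_that("global comparison is exact for identical groups and detects shifts", {
  coh <- quick_cohort(NULL, n = 6, eye_sd = 0, cell_sd = 0)
  g0 <- global_compare(coh$iamd, coh$control, "cvi")
  expect_equal(g0$median_diff, 0)
  expect_equal(g0$p_value, 1)

  # uniform -5% effect, small noise: detected with the right magnitude
  shifted <- quick_cohort(c(0, -5), n = 40, eye_sd = 1, cell_sd = 1, seed = 8)
  g1 <- global_compare(shifted$iamd, shifted$control, "cvi")
  expect_lt(g1$p_value, 0.01)
  expect_lt(abs(g1$median_diff - (-5)), 1)

  # n = 2 exercises the exact small-sample path without error
  tiny <- quick_cohort(c(0, -5), n = 2, eye_sd = 1, cell_sd = 1, seed = 3)
  g2 <- global_compare(tiny$iamd, tiny$control, "cvi")
  expect_true(is.finite(g2$p_value))

  # unmatched sizes fall back to the rank-sum test with a warning
  expect_warning(
    g3 <- global_compare(shifted$iamd[1:5], shifted$control[1:4], "cvi"),
    "rank-sum")
  expect_equal(g3$test, "rank_sum")
})

test_that("ring and sector tests behave on null and structured maps", {
  coh <- quick_cohort(NULL, n = 2, eye_sd = 0, cell_sd = 0)
  dm0 <- difference_map(coh$iamd, coh$control, "cvi")
  s0 <- sector_compare(dm0)
  expect_equal(s0$ring_test$p_value, 1)

  # a strictly decreasing radial profile separates the rings sharply
  cohr <- quick_cohort(c(-8, 10), n = 6, eye_sd = 0, cell_sd = 0, seed = 5)
  dmr <- difference_map(cohr$iamd, cohr$control, "cvi")
  sr <- sector_compare(dmr)
  expect_lt(sr$ring_test$p_value, 1e-10)
  expect_equal(nrow(sr$sector_table), 13)
})

test_that("an effect confined to the outer ring is localised by Holm-corrected sectors", {
  tmpl <- etdrs_template("OD")
  profile <- function(r) ifelse(r >= 1.5 & r < 3, -10, 0)
  coh <- generate_cohort(cohort_spec(
    n_per_group = 20, effect_profile = list(cvi = profile),
    between_eye_sd = 0, cell_noise_sd = 4, seed = 17))
  dm <- difference_map(coh$iamd, coh$control, "cvi")
  sec <- sector_compare(dm)
  tab <- sec$sector_table
  outer <- grepl("^outer_", tab$sector)
  expect_true(all(tab$p_holm[outer] < 0.05))
  inner_np <- tab$sector %in% c("central", "inner_superior", "inner_nasal",
                                "inner_inferior", "inner_temporal")
  expect_true(all(tab$p_holm[inner_np] > 0.05))
})

test_that("printed eccentricity models are recovered exactly from exact bins", {
  x <- (0:59 + 0.5) * 0.05
  y <- 3.75 * x^2 - 19.67 * x + 16.44
  fit <- choromap:::fit_bins(x, y, c(0, 3))
  expect_equal(unname(fit$quadratic), c(3.75, -19.67, 16.44),
               tolerance = 1e-9)
  expect_equal(fit$quadratic_r2, 1)
  expect_equal(fit$chosen, "quadratic")

  # noiseless linear data: quadratic gains nothing, linear is chosen
  yl <- 1.16 * x - 1.79
  fitl <- choromap:::fit_bins(x, yl, c(0, 3))
  expect_equal(unname(fitl$linear), c(1.16, -1.79), tolerance = 1e-9)
  expect_equal(fitl$chosen, "linear")

  # constant response: zero slope, R^2 = 0 by convention
  fitc <- choromap:::fit_bins(x, rep(2, 60), c(0, 3))
  expect_equal(unname(fitc$linear[1]), 0)
  expect_equal(fitc$linear_r2, 0)
  expect_equal(fitc$chosen, "linear")
})

test_that("quadratic R^2 never falls below linear R^2 (nested models)", {
  set.seed(42)
  for (i in 1:20) {
    x <- sort(runif(12, 0, 3))
    y <- rnorm(12)
    fit <- choromap:::fit_bins(x, y, c(0, 3))
    expect_gte(fit$quadratic_r2, fit$linear_r2 - 1e-12)
  }
})

test_that("model features reproduce the published crossover and vertex", {
  lin <- eccentricity_fit(linear = c(1.16, -1.79), chosen = "linear")
  f <- model_features(lin)
  expect_equal(f$root_mm, 1.79 / 1.16)
  expect_equal(f$reported$root_mm, 1.5)

  quad <- eccentricity_fit(quadratic = c(3.75, -19.67, 16.44),
                           chosen = "quadratic")
  fq <- model_features(quad)
  expect_equal(fq$vertex_mm, 19.67 / (2 * 3.75))
  expect_equal(fq$reported$vertex_mm, 2.6)

  # b = 0: vertex at the origin; degenerate slopes yield absent features
  expect_equal(model_features(eccentricity_fit(
    quadratic = c(2, 0, -1), chosen = "quadratic"))$vertex_mm, 0)
  expect_true(is.na(model_features(eccentricity_fit(
    linear = c(0, 3), chosen = "linear"))$root_mm))
})

test_that("correlations behave on identical, mirrored and coupled maps", {
  coh <- quick_cohort(c(4, -20, 16), n = 8, seed = 21)
  dm <- difference_map(coh$iamd, coh$control, "cvi")
  expect_equal(correlate_metrics(dm, dm)$rho, 1)
  neg <- dm
  neg$values <- -neg$values
  expect_equal(correlate_metrics(dm, neg)$rho, -1)

  # CVI and LA seeded with a shared luminal driver correlate strongly
  sp <- cohort_spec(n_per_group = 10,
                    effect_profile = list(cvi = c(4, -20, 16),
                                          la = c(4.54, -23.27, 12.36)),
                    seed = 3)
  coh2 <- generate_cohort(sp)
  dmc <- difference_map(coh2$iamd, coh2$control, "cvi")
  dml <- difference_map(coh2$iamd, coh2$control, "la")
  expect_gt(correlate_metrics(dmc, dml, level = "bin")$rho, 0.8)
})

test_that("normality check flags non-normal data and rejects bad input", {
  reject <- vapply(1:100, function(i) {
    set.seed(i)
    normality_check(runif(50))$p_value < 0.05
  }, TRUE)
  expect_gt(mean(reject), 0.5)
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "3 <= n")
})
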