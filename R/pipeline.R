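# Reproducible end-to-end runs: simulate -> quantify -> analyze, with
# rendered topographic maps and a manifest. All randomness flows from the
# single config seed through per-stage derived streams.

#' Configuration of a reproducible pipeline run
#'
#' Bundles every tunable of a simulate/quantify/analyze run. A run
#' re-executed from the same config reproduces all CSV/JSON outputs
#' byte-identically.
#'
#' @param seed top-level integer seed; every stage derives its stream from
#'   it.
#' @param n_per_group synthetic eyes per group.
#' @param scene a [scene_params()] template for the control group; per-eye
#'   seeds are derived from `seed`.
#' @param iamd_lumen_fraction lumen fraction (scalar or function of
#'   fovea-centred position) for the case group; defaults to the control
#'   scene's value (null effect).
#' @param n_bscans B-scans per volume.
#' @param metrics metrics to analyse, subset of `c("cvi", "ct", "la", "sa")`.
#' @param binarization a [binarization_params()].
#' @param min_quality_db,max_excluded QC thresholds.
#' @param mode percent-change formula, `"symmetric"` or `"raw"`.
#' @param paired paired (signed-rank) or unpaired (rank-sum) global test.
#' @param fit_range_mm eccentricity fit range.
#' @param bin_width_mm eccentricity bin width.
#' @param laterality sector template laterality.
#' @param out_dir output directory (created if needed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_per_group = 2L,
                       scene = scene_params(n_ascans = 96),
                       iamd_lumen_fraction = NULL,
                       n_bscans = 16L,
                       metrics = "cvi",
                       binarization = binarization_params(),
                       min_quality_db = 15,
                       max_excluded = 2,
                       mode = c("symmetric", "raw"),
                       paired = TRUE,
                       fit_range_mm = c(0, 3),
                       bin_width_mm = 0.05,
                       laterality = c("OD", "OS"),
                       out_dir = tempfile("choromap_run_")) {
  stopifnot_scalar(seed, "seed", integer = TRUE)
  stopifnot_scalar(n_per_group, "n_per_group", 2, integer = TRUE)
  stopifnot(inherits(scene, "scene_params"),
            inherits(binarization, "binarization_params"))
  stopifnot_scalar(n_bscans, "n_bscans", 1, integer = TRUE)
  metrics <- match.arg(metrics, c("cvi", "ct", "la", "sa"),
                       several.ok = TRUE)
  structure(
    list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
         scene = scene, iamd_lumen_fraction = iamd_lumen_fraction,
         n_bscans = as.integer(n_bscans), metrics = metrics,
         binarization = binarization, min_quality_db = min_quality_db,
         max_excluded = max_excluded, mode = match.arg(mode),
         paired = isTRUE(paired), fit_range_mm = fit_range_mm,
         bin_width_mm = bin_width_mm, laterality = match.arg(laterality),
         out_dir = out_dir),
    class = "run_config"
  )
}

grid_to_df <- function(grid) {
  data.frame(
    row = rep(seq_len(60), 60) - 1L,
    col = rep(seq_len(60), each = 60) - 1L,
    ct_um = as.vector(grid$ct_um),
    la_um2 = as.vector(grid$la_um2),
    sa_um2 = as.vector(grid$sa_um2),
    cvi = as.vector(grid$cvi),
    valid = as.vector(grid$valid_mask)
  )
}

#' Run the full simulate -> quantify -> analyze pipeline
#'
#' Generates `n_per_group` synthetic eyes per group (the case group differs
#' only in its lumen-fraction field), quantifies every volume on the 60x60
#' grid, and runs the group analysis per metric: difference map, sector
#' statistics, eccentricity model and model features, and the global
#' comparison. Writes per-eye metric CSVs, difference-map CSVs and PNGs,
#' sector tables, eccentricity-fit JSONs and a manifest into
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the per-metric analysis results and the
#'   manifest; side effect: files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  make_eye <- function(group, e) {
    sc <- config$scene
    sc$seed <- as.integer(derive_seed(config$seed, e,
                                      if (group == "iamd") 11L else 12L))
    if (group == "iamd" && !is.null(config$iamd_lumen_fraction)) {
      sc$lumen_fraction <- config$iamd_lumen_fraction
    }
    generate_volume(sc, n_bscans = config$n_bscans)$volume
  }

  grids <- list(iamd = list(), control = list())
  manifest_files <- character(0)
  for (group in c("control", "iamd")) {
    for (e in seq_len(config$n_per_group)) {
      vol <- make_eye(group, e)
      grid <- quantify_volume(
        vol, config$binarization,
        min_quality_db = config$min_quality_db,
        max_excluded = config$max_excluded)
      grids[[group]][[e]] <- grid
      f <- file.path(config$out_dir,
                     sprintf("eye_%s_%02d_metrics.csv", group, e))
      utils::write.csv(grid_to_df(grid), f, row.names = FALSE)
      manifest_files <- c(manifest_files, basename(f))
    }
  }

  results <- list()
  for (metric in config$metrics) {
    dm <- difference_map(grids$iamd, grids$control, metric,
                         mode = config$mode)
    sec <- sector_compare(dm, config$laterality)
    fit <- fit_eccentricity_model(dm, config$bin_width_mm,
                                  config$fit_range_mm)
    feats <- model_features(fit)
    glob <- global_compare(grids$iamd, grids$control, metric,
                           mode = config$mode, paired = config$paired)

    f_map <- file.path(config$out_dir, sprintf("diff_%s.csv", metric))
    utils::write.csv(
      data.frame(row = rep(seq_len(60), 60) - 1L,
                 col = rep(seq_len(60), each = 60) - 1L,
                 value = as.vector(dm$values),
                 valid = as.vector(dm$valid_mask)),
      f_map, row.names = FALSE)
    f_png <- file.path(config$out_dir, sprintf("diff_%s.png", metric))
    render_map(dm$values, dm$valid_mask, f_png, units = "%")
    f_sec <- file.path(config$out_dir, sprintf("sectors_%s.csv", metric))
    utils::write.csv(sec$sector_table, f_sec, row.names = FALSE)
    f_fit <- file.path(config$out_dir, sprintf("fit_%s.json", metric))
    jsonlite::write_json(
      list(linear = as.list(fit$linear),
           quadratic = as.list(fit$quadratic),
           linear_r2 = fit$linear_r2, quadratic_r2 = fit$quadratic_r2,
           chosen = fit$chosen, p_value = fit$p_value,
           features = feats[setdiff(names(feats), "model")],
           global = glob,
           ring_test = sec$ring_test),
      f_fit, digits = NA, auto_unbox = TRUE)
    manifest_files <- c(manifest_files, basename(f_map), basename(f_png),
                        basename(f_sec), basename(f_fit))
    results[[metric]] <- list(difference_map = dm, sectors = sec, fit = fit,
                              features = feats, global = glob)
  }

  manifest <- list(
    package = "choromap",
    version = as.character(utils::packageVersion("choromap")),
    seed = config$seed,
    n_per_group = config$n_per_group,
    n_bscans = config$n_bscans,
    metrics = config$metrics,
    mode = config$mode,
    outputs = manifest_files
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Render a 60x60 metric or difference map as a PNG image
#'
#' Difference maps use a diverging blue-white-red palette centred at zero
#' and symmetric about the largest absolute value; invalid cells render as
#' a distinct neutral grey. A vertical colorbar strip is attached on the
#' right, and the units plus the value range are stored in the PNG text
#' metadata.
#'
#' @param values 60x60 numeric matrix.
#' @param valid_mask 60x60 logical matrix; `FALSE` cells render neutral.
#' @param path output PNG path.
#' @param units unit string recorded with the colorbar metadata.
#' @param scale integer upscaling factor (pixels per cell).
#' @param zlim optional symmetric colour limits; defaults to the data range.
#' @return `path`, invisibly.
#' @export
render_map <- function(values, valid_mask = NULL, path, units = "%",
                       scale = 8, zlim = NULL) {
  if (!is.matrix(values) || !all(dim(values) == c(60, 60))) {
    stop("'values' must be a 60x60 matrix", call. = FALSE)
  }
  if (is.null(valid_mask)) valid_mask <- !is.na(values)
  if (!is.matrix(valid_mask) || !all(dim(valid_mask) == c(60, 60))) {
    stop("'valid_mask' must be a 60x60 logical matrix", call. = FALSE)
  }
  v <- values
  v[!valid_mask] <- NA_real_
  lim <- if (is.null(zlim)) {
    m <- max(abs(v), na.rm = TRUE)
    if (!is.finite(m) || m == 0) m <- 1
    c(-m, m)
  } else {
    zlim
  }
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  neutral <- c(0.62, 0.62, 0.62)
  to_rgb <- function(x) {
    t01 <- pmin(pmax((x - lim[1]) / (lim[2] - lim[1]), 0), 1)
    ramp(t01) / 255
  }
  img <- array(neutral[1], dim = c(60, 60, 3))
  okv <- which(!is.na(v))
  if (length(okv)) {
    cols <- to_rgb(v[okv])
    for (ch in 1:3) {
      plane <- matrix(neutral[ch], 60, 60)
      plane[okv] <- cols[, ch]
      img[, , ch] <- plane
    }
  }
  # upscale and append the colorbar strip (top = max)
  up <- function(m, s) m[rep(seq_len(nrow(m)), each = s),
                         rep(seq_len(ncol(m)), each = s), drop = FALSE]
  big <- array(0, dim = c(60 * scale, 60 * scale + 2 * scale + 4, 3))
  bar_vals <- seq(lim[2], lim[1], length.out = 60 * scale)
  bar_rgb <- to_rgb(bar_vals)
  for (ch in 1:3) {
    big[, seq_len(60 * scale), ch] <- up(img[, , ch], scale)
    big[, 60 * scale + seq_len(4), ch] <- 1           # white separator
    big[, (60 * scale + 4 + 1):(dim(big)[2]), ch] <-
      matrix(bar_rgb[, ch], nrow = 60 * scale, ncol = 2 * scale)
  }
  png::writePNG(big, path,
                text = c(units = units,
                         range = sprintf("%g..%g %s", lim[1], lim[2], units)))
  invisible(path)
}
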