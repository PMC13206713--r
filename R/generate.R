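# Synthetic macular-cube generation with per-pixel ground truth.
#
# Tissue label codes used throughout the ground truth:
#   1 retina (everything above the RPE, including vitreous)
#   2 shadow (retinal-vessel shadow band, below the inner retinal surface)
#   3 stroma, 4 lumen (choroid band), 5 sclera

LABEL_RETINA <- 1L
LABEL_SHADOW <- 2L
LABEL_STROMA <- 3L
LABEL_LUMEN <- 4L
LABEL_SCLERA <- 5L

# Shared acquisition geometry for a scene.
scene_geometry <- function(scene, n_bscans, scan_span_um = 7200) {
  h <- as.integer(round(scene$scan_depth_mm * 1000 / scene$axial_res_um))
  w <- scene$n_ascans
  ascan_spacing <- scene$scan_length_mm * 1000 / w
  bscan_spacing <- if (n_bscans > 1) scan_span_um / (n_bscans - 1) else 0
  fovea_x <- scene$scan_length_mm * 1000 / 2
  fovea_y <- if (n_bscans > 1) scan_span_um / 2 else 0
  list(
    h = h, w = w,
    ascan_spacing_um = ascan_spacing,
    bscan_spacing_um = bscan_spacing,
    x_um = (seq_len(w) - 0.5) * ascan_spacing - fovea_x,
    y_um = (seq_len(n_bscans) - 1) * bscan_spacing - fovea_y,
    fovea_xy_um = c(x = fovea_x, y = fovea_y),
    n_bscans = as.integer(n_bscans),
    scan_span_um = scan_span_um
  )
}

# Place lumen ellipses in one 120-um column chunk of the choroid band by
# rejection sampling until the realised areal fraction is within tolerance
# of the target. Overlap is allowed; the fraction is measured on the union.
fill_chunk_lumen <- function(mask, band, cols, lo, hi, target, tol,
                             ax_px_range, ay_px_range, max_attempts = 500L) {
  n_band <- sum(band[, cols, drop = FALSE])
  if (n_band == 0L || target <= 0) return(mask)
  if (target > 1) stop("'lumen_fraction' must be in [0, 1]", call. = FALSE)
  f <- sum(mask[, cols, drop = FALSE] & band[, cols, drop = FALSE]) / n_band
  attempts <- 0L
  h <- nrow(mask)
  while (f < target - tol) {
    j <- cols[sample.int(length(cols), 1L)]
    if (hi[j] < lo[j]) next
    cr <- stats::runif(1, lo[j] - 0.5, hi[j] + 0.5)
    # after repeated rejections shrink toward the small end of the vessel
    # size range (bounded at a quarter) so the remaining fraction can be
    # topped up at finer granularity; targets that stay unreachable at the
    # minimum vessel size exhaust the attempt budget and error out
    shrink <- max(0.5^(attempts %/% 100L), 0.25)
    ax <- max(stats::runif(1, ax_px_range[1], ax_px_range[2]) * shrink, 0.45)
    ay <- max(stats::runif(1, ay_px_range[1], ay_px_range[2]) * shrink, 0.45)
    cset <- cols[abs(cols - j) <= ceiling(ax)]
    rlo <- max(1L, floor(cr - ay))
    rhi <- min(h, ceiling(cr + ay))
    if (rhi < rlo) next
    rows <- rlo:rhi
    ell <- outer((rows - cr) / ay, (cset - j) / ax,
                 function(a, b) a^2 + b^2 <= 1)
    sub <- mask[rows, cset, drop = FALSE]
    bnd <- band[rows, cset, drop = FALSE]
    new_sub <- sub | (ell & bnd)
    gain <- sum(new_sub & bnd) - sum(sub & bnd)
    fc <- f + gain / n_band
    if (fc <= target + tol && gain > 0L) {
      mask[rows, cset] <- new_sub
      f <- fc
    } else {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf(
          "unreachable lumen fraction %.3f (stalled at %.3f after %d rejected placements); reduce the target or the minimum vessel size",
          target, f, max_attempts), call. = FALSE)
      }
    }
  }
  mask
}

# Render one B-scan and its ground-truth slice. Internal; the exported
# generate_bscan() wraps it with the per-scan derived seed.
render_bscan <- function(scene, geom, bscan_index0) {
  h <- geom$h
  w <- geom$w
  dz <- scene$axial_res_um
  x <- geom$x_um
  y <- geom$y_um[bscan_index0 + 1L]

  rpe_um <- as_field_fun(scene$rpe_depth_um, "rpe_depth_um")(x, rep(y, w))
  ct_um <- as_field_fun(scene$choroid_thickness_um,
                        "choroid_thickness_um")(x, rep(y, w))
  if (any(ct_um <= 0)) {
    stop("'choroid_thickness_um' must be positive everywhere", call. = FALSE)
  }
  rpe <- rpe_um / dz
  csj <- rpe + ct_um / dz
  if (any(floor(csj) > h)) {
    stop("choroid extends beyond the scan depth; reduce rpe_depth_um or choroid_thickness_um",
         call. = FALSE)
  }
  ilm <- pmax(rpe - 200 / dz, 1)

  band <- band_mask(h, rpe, csj)
  lo <- floor(rpe) + 1
  hi <- floor(csj)

  # Lumen placement, chunk by chunk (one 120-um grid-cell width at a time).
  frac_fun <- as_field_fun(scene$lumen_fraction, "lumen_fraction")
  lumen <- matrix(FALSE, h, w)
  chunk <- floor((x + 3600) / 120)
  ax_px <- scene$vessel_axes_um / geom$ascan_spacing_um
  ay_px <- scene$vessel_axes_um / dz
  for (ck in sort(unique(chunk))) {
    cols <- which(chunk == ck)
    target <- frac_fun(mean(x[cols]), y)
    if (!is.finite(target) || target < 0 || target > 1) {
      stop("'lumen_fraction' must evaluate to [0, 1]", call. = FALSE)
    }
    lumen <- fill_chunk_lumen(lumen, band, cols, lo, hi, target,
                              scene$fraction_tol, ax_px, ay_px)
  }

  # Base intensities by tissue; the choroid band is strictly bimodal.
  rows <- matrix(seq_len(h), h, w)
  img <- matrix(20, h, w)                       # vitreous
  retina <- rows > rep(floor(ilm), each = h) & rows <= rep(floor(rpe), each = h)
  sclera <- rows > rep(hi, each = h)
  img[retina] <- 110
  img[sclera] <- 150
  img[band] <- scene$stroma_intensity
  img[lumen] <- scene$lumen_intensity

  # Vertical retinal-vessel shadow bands attenuate everything below the ILM.
  shadow_cols <- integer(0)
  if (scene$n_shadow_columns > 0L && scene$shadow_width_px <= w) {
    starts <- sample.int(w - scene$shadow_width_px + 1L,
                         scene$n_shadow_columns, replace = TRUE)
    shadow_cols <- sort(unique(unlist(
      lapply(starts, function(s) s:(s + scene$shadow_width_px - 1L)))))
    below_ilm <- rows[, shadow_cols, drop = FALSE] >
      rep(floor(ilm[shadow_cols]), each = h)
    img[, shadow_cols][below_ilm] <-
      img[, shadow_cols][below_ilm] * scene$shadow_attenuation
  }

  if (scene$noise_sd > 0) {
    img <- img + stats::rnorm(h * w, sd = scene$noise_sd)
  }
  img <- round(pmin(pmax(img, 0), 255))

  labels <- matrix(LABEL_RETINA, h, w)
  labels[band] <- LABEL_STROMA
  labels[lumen] <- LABEL_LUMEN
  labels[sclera] <- LABEL_SCLERA
  if (length(shadow_cols)) {
    lab_sub <- labels[, shadow_cols, drop = FALSE]
    lab_sub[rows[, shadow_cols, drop = FALSE] >
              rep(floor(ilm[shadow_cols]), each = h)] <- LABEL_SHADOW
    labels[, shadow_cols] <- lab_sub
  }

  list(
    image = img,
    labels = labels,
    lumen_mask = lumen,       # pre-shadow tissue truth
    band_mask = band,
    rpe_curve = rpe,
    csj_curve = csj,
    shadow_columns = shadow_cols,
    y_um = y
  )
}

#' Generate one synthetic B-scan with ground truth
#'
#' Renders a single cross-sectional B-scan of the synthetic macular cube:
#' retina above the RPE, a bimodal choroid band (dark lumen ellipses on
#' brighter stroma) between the RPE and choroidoscleral boundary curves,
#' sclera below, vertical vessel-shadow bands, and additive noise (applied
#' last, clipped to `[0, 255]` and rounded to integer grey levels). The
#' realised lumen areal fraction within the choroid band is within
#' `scene$fraction_tol` of the target, enforced per 120-um column chunk.
#'
#' @param scene a [scene_params()] object.
#' @param bscan_index 0-based index in `[0, n_bscans)`.
#' @param n_bscans number of B-scans in the cube the scan belongs to.
#' @param scan_span_um vertical extent covered by the B-scan stack, um.
#' @return A list with `image` (H x W integer grey matrix, H =
#'   `round(1800/3.9)` rows under the default protocol) and `truth`, a
#'   ground-truth slice holding per-pixel `labels`, the pre-shadow
#'   `lumen_mask` and `band_mask`, real-valued `rpe_curve` / `csj_curve`
#'   boundary rows, and `shadow_columns`.
#' @export
generate_bscan <- function(scene, bscan_index, n_bscans = 61,
                           scan_span_um = 7200) {
  stopifnot(inherits(scene, "scene_params"))
  stopifnot_scalar(bscan_index, "bscan_index", 0, n_bscans - 1, integer = TRUE)
  geom <- scene_geometry(scene, n_bscans, scan_span_um)
  slice <- with_seed(derive_seed(scene$seed, bscan_index, 1L),
                     render_bscan(scene, geom, as.integer(bscan_index)))
  list(image = slice$image, truth = slice[-1])
}

#' Generate a synthetic macular-cube volume with ground truth
#'
#' Builds a full macular cube under the default acquisition protocol
#' (61 B-scans, 8.6 mm scan length, 1.8 mm depth at 3.9 um axial
#' resolution, B-scan stack spanning 7200 um) and its per-pixel /
#' per-cell ground truth. The fovea sits at the geometric centre of the
#' volume. Two calls with the same scene seed are bit-identical.
#'
#' @inheritParams generate_bscan
#' @param n_bscans number of B-scans (default 61).
#' @return A list with `volume`, an [oct_volume] object, and `truth`, a
#'   `ground_truth` object with `label_stack`, `lumen_stack`, `band_stack`,
#'   `shadow_columns`, and `cell_truth` (60x60 true `ct_um`, `la_um2`,
#'   `sa_um2`, `cvi` matrices computed from the tissue labels).
#' @export
generate_volume <- function(scene, n_bscans = 61, scan_span_um = 7200) {
  stopifnot(inherits(scene, "scene_params"))
  stopifnot_scalar(n_bscans, "n_bscans", 1, integer = TRUE)
  geom <- scene_geometry(scene, n_bscans, scan_span_um)

  slices <- lapply(seq_len(n_bscans) - 1L, function(i0) {
    with_seed(derive_seed(scene$seed, i0, 1L), render_bscan(scene, geom, i0))
  })

  quality <- scene$quality_db
  if (length(quality) == 1L) quality <- rep(quality, n_bscans)
  if (length(quality) != n_bscans) {
    stop("'quality_db' must be scalar or length n_bscans", call. = FALSE)
  }

  volume <- oct_volume(
    images = lapply(slices, `[[`, "image"),
    ascan_spacing_um = geom$ascan_spacing_um,
    bscan_spacing_um = geom$bscan_spacing_um,
    axial_res_um = scene$axial_res_um,
    quality_db = quality,
    laterality = scene$laterality,
    fovea_xy_um = geom$fovea_xy_um,
    rpe_curve = do.call(rbind, lapply(slices, `[[`, "rpe_curve")),
    csj_curve = do.call(rbind, lapply(slices, `[[`, "csj_curve"))
  )

  truth <- structure(
    list(
      label_stack = lapply(slices, `[[`, "labels"),
      lumen_stack = lapply(slices, `[[`, "lumen_mask"),
      band_stack = lapply(slices, `[[`, "band_mask"),
      shadow_columns = lapply(slices, `[[`, "shadow_columns"),
      cell_truth = truth_cell_metrics(slices, geom, scene)
    ),
    class = "ground_truth"
  )
  list(volume = volume, truth = truth)
}

# True per-cell CT/LA/SA/CVI from the tissue labels (pre-shadow), using the
# same grid mapping and aggregation conventions as the analysis pipeline.
truth_cell_metrics <- function(slices, geom, scene) {
  px_area <- geom$ascan_spacing_um * scene$axial_res_um
  lum <- matrix(0, 60, 60)
  tot <- matrix(0, 60, 60)
  ct_vals <- vector("list", 3600L)
  any_sample <- matrix(FALSE, 60, 60)
  gx <- grid_index(geom$x_um, rep(0, geom$w))$col
  for (s in seq_along(slices)) {
    sl <- slices[[s]]
    row0 <- grid_index(0, sl$y_um)$row
    if (is.na(row0)) next
    cols <- which(!is.na(gx))
    lum_col <- colSums(sl$lumen_mask[, cols, drop = FALSE])
    tot_col <- colSums(sl$band_mask[, cols, drop = FALSE])
    ct_col <- (sl$csj_curve[cols] - sl$rpe_curve[cols]) * scene$axial_res_um
    key <- gx[cols]
    for (cell in unique(key)) {
      i <- row0 + 1L
      j <- cell + 1L
      sel <- key == cell
      lum[i, j] <- lum[i, j] + sum(lum_col[sel])
      tot[i, j] <- tot[i, j] + sum(tot_col[sel])
      idx <- (j - 1L) * 60L + i
      ct_vals[[idx]] <- c(ct_vals[[idx]], ct_col[sel])
      any_sample[i, j] <- TRUE
    }
  }
  ct <- matrix(NA_real_, 60, 60)
  ct[any_sample] <- vapply(which(any_sample), function(idx) {
    stats::median(ct_vals[[idx]])
  }, 0)
  la <- ifelse(any_sample, lum * px_area, NA_real_)
  sa <- ifelse(any_sample, (tot - lum) * px_area, NA_real_)
  cvi <- ifelse(any_sample & tot > 0, lum / tot, NA_real_)
  cvi[any_sample & tot > 0 & lum == 0] <- 0
  list(ct_um = ct, la_um2 = la, sa_um2 = sa, cvi = cvi,
       sampled = any_sample)
}

#' Generate a synthetic two-group cohort of per-eye metric grids
#'
#' Draws `n_per_group` case eyes and `n_per_group` control eyes at grid
#' level: each control eye's cell value is `baseline * exp(eye effect +
#' cell noise)`; each case eye is additionally scaled per cell by the ratio
#' `rho(r)` that makes the true symmetric percent change between the group
#' median cells equal the prescribed effect profile at that cell's
#' eccentricity `r`, i.e. `rho = (2 + d) / (2 - d)` with `d =
#' profile(r) / 100`. Eye-level and cell-level variation are multiplicative
#' log-normal, so all metric values stay strictly positive.
#'
#' The profile is evaluated at the centre of each cell's 0.05-mm
#' eccentricity bin (the resolution of the eccentricity analysis), so the
#' embedded truth is exactly representable by the binned regression: with
#' noise switched off, [fit_eccentricity_model()] recovers a polynomial
#' profile to machine precision.
#'
#' @param spec a [cohort_spec()] object.
#' @return A list of class `synthetic_cohort` with `iamd` and `control`
#'   (lists of [cell_metrics_grid] objects, one per eye) and `truth`
#'   (embedded per-metric true percent-change grids, profile definitions and
#'   the cell eccentricities) for recovery tests.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  metrics <- names(spec$baseline_grid)
  cc <- grid_cell_centers()
  profiles <- lapply(metrics, function(m) as_profile_fun(spec$effect_profile[[m]]))
  names(profiles) <- metrics
  # embed at the analysis resolution: centre of each cell's 0.05-mm bin
  r_embed <- (eccentricity_bin(as.vector(cc$r_mm)) + 0.5) * 0.05
  true_change <- lapply(profiles, function(f) {
    d <- matrix(f(r_embed), 60, 60)
    if (any(!is.finite(d)) || any(abs(d) >= 200)) {
      stop("effect profile must stay within (-200, 200) percent (positive metrics)",
           call. = FALSE)
    }
    d
  })
  rho <- lapply(true_change, function(d) (2 + d / 100) / (2 - d / 100))

  sd_eye <- spec$between_eye_sd / 100
  sd_cell <- spec$cell_noise_sd / 100

  make_eye <- function(group) {
    eps <- stats::rnorm(1, sd = sd_eye)
    vals <- lapply(metrics, function(m) {
      eta <- matrix(stats::rnorm(3600, sd = sd_cell), 60, 60)
      v <- spec$baseline_grid[[m]] * exp(eps + eta)
      if (group == "iamd") v <- v * rho[[m]]
      v
    })
    names(vals) <- metrics
    cell_metrics_grid(
      ct_um = vals[["ct"]], la_um2 = vals[["la"]],
      sa_um2 = vals[["sa"]], cvi = vals[["cvi"]],
      valid_mask = matrix(TRUE, 60, 60)
    )
  }

  with_seed(spec$seed, {
    control <- lapply(seq_len(spec$n_per_group), function(e) make_eye("control"))
    iamd <- lapply(seq_len(spec$n_per_group), function(e) make_eye("iamd"))
    structure(
      list(
        iamd = iamd, control = control,
        truth = list(
          metrics = metrics,
          effect_profile = spec$effect_profile,
          true_change = true_change,
          r_mm = cc$r_mm
        )
      ),
      class = "synthetic_cohort"
    )
  })
}
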