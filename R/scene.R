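#' Parameters of a synthetic macular-cube scene
#'
#' Describes the geometry, texture and artefacts of a synthetic OCT macular
#' cube: a smooth retinal pigment epithelium (RPE) surface, a choroid band of
#' prescribed thickness whose texture is bimodal (dark vessel lumen ellipses
#' on a brighter stromal background), vertical retinal-vessel shadow bands,
#' and additive speckle-like noise. The acquisition geometry follows a
#' standard high-density macular cube protocol: 61 B-scans, 8.6 mm scan
#' length, 1.8 mm scan depth at 3.9 um axial resolution.
#'
#' The target lumen areal fraction is realised by rejection sampling of
#' ellipses independently within each 120-um-wide column chunk of the choroid
#' band (the width of one grid cell), so the realised fraction is within
#' `fraction_tol` of the target both per B-scan and per grid cell.
#' `lumen_fraction` may be a scalar or a `function(x_um, y_um)` of
#' fovea-centred position, which lets a spatial effect profile be embedded at
#' image level.
#'
#' @param rpe_depth_um RPE boundary depth in um; scalar or
#'   `function(x_um, y_um)` (fovea-centred coordinates).
#' @param choroid_thickness_um choroidal thickness (CT) field in um; scalar or
#'   function; must be positive everywhere it is evaluated.
#' @param lumen_fraction target lumen areal fraction within the choroid band,
#'   in `[0, 1]`; scalar or function of position.
#' @param stroma_intensity,lumen_intensity mean grey levels (0-255) of stroma
#'   and lumen; lumen must be darker than stroma.
#' @param noise_sd standard deviation of additive Gaussian noise (grey
#'   levels), applied last and clipped to `[0, 255]`.
#' @param vessel_axes_um length-2 range of ellipse semi-axes in um.
#' @param n_shadow_columns number of retinal-vessel shadow bands per B-scan.
#' @param shadow_attenuation multiplicative attenuation in `(0, 1]` applied to
#'   all pixels below the inner retinal surface within a shadow band.
#' @param shadow_width_px width of each shadow band in A-scan columns.
#' @param n_ascans A-scans per B-scan.
#' @param scan_length_mm B-scan length in mm.
#' @param scan_depth_mm axial scan depth in mm.
#' @param axial_res_um axial resolution, um per pixel row.
#' @param quality_db simulated per-B-scan quality score (dB).
#' @param laterality `"OD"` or `"OS"`.
#' @param fraction_tol tolerance on the realised lumen fraction.
#' @param seed integer RNG seed; identical seeds give bit-identical volumes.
#'
#' @return An object of class `scene_params`.
#' @seealso [generate_bscan()], [generate_volume()]
#' @export
scene_params <- function(rpe_depth_um = 700,
                         choroid_thickness_um = 280,
                         lumen_fraction = 0.65,
                         stroma_intensity = 180,
                         lumen_intensity = 60,
                         noise_sd = 20,
                         vessel_axes_um = c(15, 50),
                         n_shadow_columns = 3,
                         shadow_attenuation = 0.5,
                         shadow_width_px = 5,
                         n_ascans = 512,
                         scan_length_mm = 8.6,
                         scan_depth_mm = 1.8,
                         axial_res_um = 3.9,
                         quality_db = 30,
                         laterality = c("OD", "OS"),
                         fraction_tol = 0.01,
                         seed = 1L) {
  stopifnot_scalar(stroma_intensity, "stroma_intensity", 0, 255)
  stopifnot_scalar(lumen_intensity, "lumen_intensity", 0, 255)
  if (lumen_intensity >= stroma_intensity) {
    stop("'lumen_intensity' must be strictly less than 'stroma_intensity'",
         call. = FALSE)
  }
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  if (!is.numeric(vessel_axes_um) || length(vessel_axes_um) != 2L ||
      any(vessel_axes_um <= 0) || vessel_axes_um[1] > vessel_axes_um[2]) {
    stop("'vessel_axes_um' must be an increasing positive length-2 range",
         call. = FALSE)
  }
  stopifnot_scalar(n_shadow_columns, "n_shadow_columns", 0, integer = TRUE)
  stopifnot_scalar(shadow_attenuation, "shadow_attenuation", lo = 1e-6, hi = 1)
  stopifnot_scalar(shadow_width_px, "shadow_width_px", 1, integer = TRUE)
  stopifnot_scalar(n_ascans, "n_ascans", 8, integer = TRUE)
  stopifnot_scalar(scan_length_mm, "scan_length_mm", 0.1)
  stopifnot_scalar(scan_depth_mm, "scan_depth_mm", 0.1)
  stopifnot_scalar(axial_res_um, "axial_res_um", 0.1)
  stopifnot_scalar(quality_db, "quality_db", 0)
  stopifnot_scalar(fraction_tol, "fraction_tol", 1e-4, 0.5)
  stopifnot_scalar(seed, "seed", integer = TRUE)
  if (is.numeric(lumen_fraction) && length(lumen_fraction) == 1L &&
      (lumen_fraction < 0 || lumen_fraction > 1)) {
    stop("'lumen_fraction' must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      rpe_depth_um = rpe_depth_um,
      choroid_thickness_um = choroid_thickness_um,
      lumen_fraction = lumen_fraction,
      stroma_intensity = stroma_intensity,
      lumen_intensity = lumen_intensity,
      noise_sd = noise_sd,
      vessel_axes_um = vessel_axes_um,
      n_shadow_columns = as.integer(n_shadow_columns),
      shadow_attenuation = shadow_attenuation,
      shadow_width_px = as.integer(shadow_width_px),
      n_ascans = as.integer(n_ascans),
      scan_length_mm = scan_length_mm,
      scan_depth_mm = scan_depth_mm,
      axial_res_um = axial_res_um,
      quality_db = quality_db,
      laterality = match.arg(laterality),
      fraction_tol = fraction_tol,
      seed = as.integer(seed)
    ),
    class = "scene_params"
  )
}

#' Specification of a synthetic two-group cohort
#'
#' Defines a cohort of eyes in two groups (cases vs controls) whose per-cell
#' choroidal metrics are drawn around a 60x60 baseline grid, with the group
#' difference following a prescribed eccentricity profile of true symmetric
#' percent change. Eye-level and cell-level variation are multiplicative
#' log-normal, which keeps all metrics strictly positive so the symmetric
#' percent-change denominator is never zero.
#'
#' The effect profile for a metric is either `NULL` (no effect), a length-2
#' numeric `c(m, k)` for a linear profile `m*r + k`, a length-3 numeric
#' `c(a, b, c)` for a quadratic profile `a*r^2 + b*r + c`, or a
#' `function(r_mm)`; `r` is eccentricity in mm and the value is the true
#' symmetric percent change at that eccentricity (must stay in (-200, 200)).
#'
#' @param n_per_group eyes per group (>= 2).
#' @param baseline_grid named list of 60x60 matrices (or scalars) of baseline
#'   cell values per metric; defaults cover `ct`, `cvi`, `la`, `sa` with
#'   homogeneous, strictly positive values.
#' @param effect_profile named list of per-metric effect profiles (see
#'   Details); metrics absent from the list get a null effect.
#' @param between_eye_sd SD of the eye-level log-normal random effect, as a
#'   percentage (e.g. 3 means the eye factor is `exp(N(0, 0.03))`).
#' @param cell_noise_sd SD of the independent per-cell log-normal noise, as a
#'   percentage.
#' @param seed integer RNG seed.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_per_group = 40,
                        baseline_grid = NULL,
                        effect_profile = list(),
                        between_eye_sd = 3,
                        cell_noise_sd = 6,
                        seed = 1L) {
  stopifnot_scalar(n_per_group, "n_per_group", 2, integer = TRUE)
  stopifnot_scalar(between_eye_sd, "between_eye_sd", 0)
  stopifnot_scalar(cell_noise_sd, "cell_noise_sd", 0)
  stopifnot_scalar(seed, "seed", integer = TRUE)
  defaults <- list(ct = 280, cvi = 0.65, la = 21840, sa = 11760)
  if (is.null(baseline_grid)) baseline_grid <- defaults
  if (!is.list(baseline_grid) || is.null(names(baseline_grid))) {
    stop("'baseline_grid' must be a named list of matrices or scalars",
         call. = FALSE)
  }
  baseline_grid <- lapply(baseline_grid, function(b) {
    if (is.numeric(b) && length(b) == 1L) b <- matrix(b, 60, 60)
    if (!is.matrix(b) || !all(dim(b) == c(60, 60))) {
      stop("baseline grids must be 60x60 matrices or scalars", call. = FALSE)
    }
    if (any(b <= 0)) {
      stop("baseline grid values must be strictly positive", call. = FALSE)
    }
    b
  })
  if (!is.list(effect_profile)) {
    stop("'effect_profile' must be a named list", call. = FALSE)
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      baseline_grid = baseline_grid,
      effect_profile = effect_profile,
      between_eye_sd = between_eye_sd,
      cell_noise_sd = cell_noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Normalise an effect-profile entry to a vectorised function of r (mm).
as_profile_fun <- function(p) {
  if (is.null(p)) {
    return(function(r) rep(0, length(r)))
  }
  if (is.function(p)) {
    return(p)
  }
  if (is.numeric(p) && length(p) == 2L) {
    return(function(r) p[1] * r + p[2])
  }
  if (is.numeric(p) && length(p) == 3L) {
    return(function(r) p[1] * r^2 + p[2] * r + p[3])
  }
  stop("effect profile must be NULL, c(m, k), c(a, b, c) or a function(r_mm)",
       call. = FALSE)
}
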