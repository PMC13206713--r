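#' OCT macular-cube volume container
#'
#' Holds one eye's macular cube: the B-scan image stack, acquisition
#' geometry, per-scan quality scores, laterality, fovea position and the
#' two choroid boundary segmentations (RPE and choroidoscleral junction,
#' CSJ). Choroidal thickness is the RPE-to-CSJ distance. Boundary curves are
#' stored as real-valued pixel rows, so sub-pixel segmentations are
#' preserved and CT is computed on the real values, not rounded rows.
#'
#' @param images list of H x W numeric matrices (grey levels 0-255), one per
#'   B-scan.
#' @param ascan_spacing_um um per A-scan (image column).
#' @param bscan_spacing_um um between consecutive B-scans (0 for a
#'   single-scan volume).
#' @param axial_res_um um per pixel row (default 3.9).
#' @param quality_db per-B-scan quality score in dB.
#' @param laterality `"OD"` or `"OS"`.
#' @param fovea_xy_um fovea position in volume coordinates, um from the first
#'   A-scan (`x`) and first B-scan (`y`).
#' @param rpe_curve,csj_curve n_bscans x W matrices of boundary depths in
#'   pixel rows; `csj_curve >= rpe_curve` everywhere.
#' @param opacity_flag manual flag for media opacity / poor choroid
#'   visibility (recorded metadata, not detected).
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(images, ascan_spacing_um, bscan_spacing_um,
                       axial_res_um = 3.9, quality_db, laterality = "OD",
                       fovea_xy_um, rpe_curve, csj_curve,
                       opacity_flag = FALSE) {
  if (!is.list(images) || !length(images) || !all(vapply(images, is.matrix, TRUE))) {
    stop("format error in 'images': expected a nonempty list of matrices",
         call. = FALSE)
  }
  n <- length(images)
  h <- nrow(images[[1]])
  w <- ncol(images[[1]])
  if (!all(vapply(images, function(m) all(dim(m) == c(h, w)), TRUE))) {
    stop("format error in 'images': B-scans differ in shape", call. = FALSE)
  }
  stopifnot_scalar(ascan_spacing_um, "ascan_spacing_um", lo = 1e-6)
  if (n > 1) stopifnot_scalar(bscan_spacing_um, "bscan_spacing_um", lo = 1e-6)
  stopifnot_scalar(axial_res_um, "axial_res_um", lo = 1e-6)
  if (length(quality_db) != n || any(!is.finite(quality_db))) {
    stop("format error in 'quality_db': one finite value per B-scan required",
         call. = FALSE)
  }
  if (!laterality %in% c("OD", "OS")) {
    stop("format error in 'laterality': must be \"OD\" or \"OS\"", call. = FALSE)
  }
  if (length(fovea_xy_um) != 2L || any(!is.finite(fovea_xy_um))) {
    stop("format error in 'fovea_xy_um': expected c(x, y) in um", call. = FALSE)
  }
  if (missing(rpe_curve) || is.null(rpe_curve)) {
    stop("format error in 'rpe_curve': boundary segmentations are required inputs",
         call. = FALSE)
  }
  if (missing(csj_curve) || is.null(csj_curve)) {
    stop("format error in 'csj_curve': boundary segmentations are required inputs",
         call. = FALSE)
  }
  rpe_curve <- as.matrix(rpe_curve)
  csj_curve <- as.matrix(csj_curve)
  if (!all(dim(rpe_curve) == c(n, w)) || !all(dim(csj_curve) == c(n, w))) {
    stop("format error in boundary curves: expected n_bscans x width matrices",
         call. = FALSE)
  }
  if (any(csj_curve < rpe_curve)) {
    stop("format error in boundary curves: csj_curve < rpe_curve at some A-scan",
         call. = FALSE)
  }
  structure(
    list(
      images = images,
      ascan_spacing_um = as.numeric(ascan_spacing_um),
      bscan_spacing_um = as.numeric(bscan_spacing_um),
      axial_res_um = as.numeric(axial_res_um),
      quality_db = as.numeric(quality_db),
      laterality = laterality,
      fovea_xy_um = c(x = as.numeric(fovea_xy_um[[1]]),
                      y = as.numeric(fovea_xy_um[[2]])),
      rpe_curve = rpe_curve,
      csj_curve = csj_curve,
      opacity_flag = isTRUE(opacity_flag)
    ),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf(
    "<oct_volume> %d B-scans of %d x %d px (%s)\n  A-scan %.2f um, B-scan %.1f um, axial %.2f um; quality %.1f-%.1f dB\n",
    length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]), x$laterality,
    x$ascan_spacing_um, x$bscan_spacing_um, x$axial_res_um,
    min(x$quality_db), max(x$quality_db)))
  invisible(x)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write / read an OCT volume in the open exchange format
#'
#' The exchange format is a multi-page 8-bit grayscale TIFF (one page per
#' B-scan) plus a JSON metadata sidecar of the same basename holding the
#' geometry, quality scores, laterality, fovea position and the two boundary
#' curves at full precision. The write -> read round trip is lossless for
#' pixel data and every metadata field.
#'
#' @param volume an [oct_volume] object.
#' @param path path to the TIFF file; the sidecar is written next to it with
#'   a `.json` extension.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   [oct_volume].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  tiff::writeTIFF(lapply(volume$images, function(m) m / 255), path,
                  bits.per.sample = 8L, compression = "none")
  meta <- list(
    n_bscans = length(volume$images),
    height = nrow(volume$images[[1]]),
    width = ncol(volume$images[[1]]),
    ascan_spacing_um = volume$ascan_spacing_um,
    bscan_spacing_um = volume$bscan_spacing_um,
    axial_res_um = volume$axial_res_um,
    quality_db = volume$quality_db,
    laterality = volume$laterality,
    fovea_xy_um = as.list(volume$fovea_xy_um),
    opacity_flag = volume$opacity_flag,
    rpe_curve = volume$rpe_curve,
    csj_curve = volume$csj_curve
  )
  # 17 significant digits: doubles survive the write -> read round trip
  jsonlite::write_json(meta, sidecar_path(path), digits = I(17),
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("format error: image stack '%s' not found", path),
         call. = FALSE)
  }
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop(sprintf("format error: metadata sidecar '%s' is missing", sp),
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$n_bscans) || meta$n_bscans != length(pages)) {
    stop(sprintf(
      "format error in 'n_bscans': sidecar declares %s B-scans but the stack has %d pages",
      as.character(meta$n_bscans), length(pages)), call. = FALSE)
  }
  for (fld in c("rpe_curve", "csj_curve")) {
    if (is.null(meta[[fld]])) {
      stop(sprintf(
        "format error in '%s': boundary curves are required inputs; supply the segmentation",
        fld), call. = FALSE)
    }
  }
  images <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    round(p * 255)
  })
  oct_volume(
    images = images,
    ascan_spacing_um = meta$ascan_spacing_um,
    bscan_spacing_um = meta$bscan_spacing_um,
    axial_res_um = meta$axial_res_um,
    quality_db = meta$quality_db,
    laterality = meta$laterality,
    fovea_xy_um = c(meta$fovea_xy_um$x, meta$fovea_xy_um$y),
    rpe_curve = matrix(unlist(meta$rpe_curve), nrow = meta$n_bscans,
                       byrow = FALSE),
    csj_curve = matrix(unlist(meta$csj_curve), nrow = meta$n_bscans,
                       byrow = FALSE),
    opacity_flag = isTRUE(meta$opacity_flag)
  )
}

#' Quality-control filter for a macular cube
#'
#' Marks B-scans whose quality score falls strictly below the threshold
#' (a scan at exactly 15.0 dB passes) and rejects the whole volume when the
#' number of excluded scans exceeds `max_excluded` (i.e. three or more
#' exclusions under the defaults). Excluded scans are dropped from all
#' downstream aggregation: their grid rows become invalid, never zero.
#' The decision is a pure function of `quality_db`.
#'
#' @param volume an [oct_volume].
#' @param min_quality_db minimum acceptable quality (dB); default 15.
#' @param max_excluded maximum tolerated number of excluded B-scans.
#' @return An object of class `qc_report`: `excluded_bscans` (1-based
#'   indices), `volume_accepted`, and a human-readable `reason`.
#' @export
qc_filter <- function(volume, min_quality_db = 15, max_excluded = 2) {
  stopifnot(inherits(volume, "oct_volume"))
  excluded <- which(volume$quality_db < min_quality_db)
  accepted <- length(excluded) <= max_excluded
  reason <- if (accepted && !length(excluded)) {
    "all B-scans meet the quality threshold"
  } else if (accepted) {
    sprintf("%d B-scan(s) below %.1f dB excluded; volume retained",
            length(excluded), min_quality_db)
  } else {
    sprintf("%d B-scans below %.1f dB (more than %d): volume rejected",
            length(excluded), min_quality_db, max_excluded)
  }
  structure(
    list(excluded_bscans = excluded, volume_accepted = accepted,
         reason = reason),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> accepted = %s; %s\n", x$volume_accepted, x$reason))
  invisible(x)
}

#' Write ground truth as a label TIFF stack and a cell-truth CSV
#'
#' @param truth a `ground_truth` object from [generate_volume()].
#' @param path path to the label TIFF; the cell-truth table is written next
#'   to it as `<basename>_cells.csv` with one row per grid cell.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  tiff::writeTIFF(lapply(truth$label_stack, function(m) m / 255), path,
                  bits.per.sample = 8L, compression = "none")
  ct <- truth$cell_truth
  df <- data.frame(
    row = rep(seq_len(60), 60) - 1L,
    col = rep(seq_len(60), each = 60) - 1L,
    ct_um = as.vector(ct$ct_um),
    la_um2 = as.vector(ct$la_um2),
    sa_um2 = as.vector(ct$sa_um2),
    cvi = as.vector(ct$cvi)
  )
  utils::write.csv(
    df, paste0(tools::file_path_sans_ext(path), "_cells.csv"),
    row.names = FALSE)
  invisible(path)
}
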