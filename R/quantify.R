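# Lumen/stroma binarization and per-cell choroidal metrics.

#' Parameters for multiscale median-cut binarization
#'
#' The choroid band is quantized by median-cut: the intensity bucket with
#' the widest range is recursively split at its median value until
#' `n_levels` buckets exist (buckets that have collapsed to a single value
#' stop splitting). The darkest half of the resulting buckets is labelled
#' lumen. Because splitting always refines the widest bucket, the split
#' thresholds concentrate at the valley between the hypo-reflective lumen
#' mode and the brighter stroma mode, so the labelled fraction tracks the
#' true lumen fraction rather than a fixed quantile. The pass runs at
#' several window widths (in A-scan columns; `Inf` = whole region) and the
#' per-pixel labels are combined across scales.
#'
#' @param n_levels number of buckets; a power of two, >= 2 (default 4).
#' @param window_widths_px window widths in columns for the multiscale pass.
#' @param combine_rule how per-scale labels merge: `"majority"` (default),
#'   `"any"`, or `"all"`.
#' @return An object of class `binarization_params`.
#' @export
binarization_params <- function(n_levels = 4,
                                window_widths_px = c(32, 64, Inf),
                                combine_rule = c("majority", "any", "all")) {
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 2 ||
      n_levels != round(n_levels) || bitwAnd(as.integer(n_levels), as.integer(n_levels) - 1L) != 0L) {
    stop("'n_levels' must be a power of two >= 2", call. = FALSE)
  }
  if (!is.numeric(window_widths_px) || !length(window_widths_px) ||
      any(window_widths_px[is.finite(window_widths_px)] < 1)) {
    stop("'window_widths_px' must be positive widths (Inf = whole region)",
         call. = FALSE)
  }
  structure(
    list(n_levels = as.integer(n_levels),
         window_widths_px = window_widths_px,
         combine_rule = match.arg(combine_rule)),
    class = "binarization_params"
  )
}

# Median-cut lumen labels for one pixel-intensity vector. Returns a logical
# vector (TRUE = lumen). A constant vector yields all-stroma (no valley).
median_cut_lumen <- function(v, n_levels) {
  if (!length(v)) return(logical(0))
  if (diff(range(v)) == 0) return(rep(FALSE, length(v)))
  sv <- sort(v)
  n <- length(sv)
  buckets <- list(c(1L, n))
  while (length(buckets) < n_levels) {
    rngs <- vapply(buckets, function(b) sv[b[2]] - sv[b[1]], 0)
    if (max(rngs) == 0) break
    i <- which.max(rngs)
    b <- buckets[[i]]
    vals <- sv[b[1]:b[2]]
    m <- stats::median(vals)
    p <- b[1] - 1L + sum(vals <= m)
    if (p >= b[2]) p <- b[1] - 1L + sum(vals < m)
    if (p < b[1]) break   # cannot separate (should not occur when range > 0)
    buckets[[i]] <- c(b[1], p)
    buckets[[length(buckets) + 1L]] <- c(p + 1L, b[2])
  }
  if (length(buckets) < 2L) return(rep(FALSE, length(v)))
  ord <- order(vapply(buckets, `[`, 0L, 1L))
  buckets <- buckets[ord]
  n_dark <- floor(length(buckets) / 2)
  threshold <- sv[buckets[[n_dark]][2]]
  v <= threshold
}

#' Binarize the choroid band into lumen and stroma
#'
#' Applies multiscale median-cut quantization (see [binarization_params()])
#' to the choroid band of one B-scan: within each column window at each
#' scale, band pixels are bucketed by recursive median splits and the
#' darkest half of buckets is labelled lumen; labels from all scales are
#' combined per pixel by the configured rule. The mask is restricted to the
#' band between the RPE and choroidoscleral boundary curves.
#'
#' A constant-intensity band carries no lumen/stroma contrast; by
#' convention it is labelled all-stroma, with a warning.
#'
#' @param bscan H x W numeric matrix of grey levels.
#' @param rpe_curve,csj_curve per-A-scan boundary depths in pixel rows
#'   (real-valued).
#' @param params a [binarization_params()] object.
#' @return Logical H x W matrix, TRUE = lumen (FALSE outside the band).
#' @export
binarize_choroid <- function(bscan, rpe_curve, csj_curve,
                             params = binarization_params()) {
  stopifnot(is.matrix(bscan),
            length(rpe_curve) == ncol(bscan),
            length(csj_curve) == ncol(bscan))
  h <- nrow(bscan)
  w <- ncol(bscan)
  band <- band_mask(h, rpe_curve, csj_curve)
  if (!any(band)) {
    stop("choroid band is empty at every A-scan", call. = FALSE)
  }
  if (diff(range(bscan[band])) == 0) {
    warning("constant-intensity choroid band: labelling all pixels stroma",
            call. = FALSE)
    return(matrix(FALSE, h, w))
  }
  widths <- params$window_widths_px
  widths[!is.finite(widths)] <- w
  widths <- pmin(as.integer(widths), w)
  votes <- matrix(0L, h, w)
  for (wd in widths) {
    for (s in seq(1L, w, by = wd)) {
      cols <- s:min(s + wd - 1L, w)
      sel <- band[, cols, drop = FALSE]
      if (!any(sel)) next
      px <- which(sel)
      lab <- median_cut_lumen(bscan[, cols, drop = FALSE][px], params$n_levels)
      sub <- votes[, cols, drop = FALSE]
      sub[px] <- sub[px] + as.integer(lab)
      votes[, cols] <- sub
    }
  }
  k <- length(widths)
  mask <- switch(params$combine_rule,
                 majority = votes > k / 2,
                 any = votes >= 1L,
                 all = votes == k)
  mask & band
}

#' Detect retinal-vessel shadow columns in a B-scan
#'
#' Retinal vessels cast vertical attenuation bands over everything beneath
#' them, corrupting choroidal intensities. Every A-scan column is
#' summarised by the 40% trimmed mean of its intensities below the RPE:
#' the trimmed mean is dominated by the stable scleral reflectance, so
#' it responds to broadband attenuation of the whole column but not to how
#' much dark vessel lumen (or bright stroma) the column happens to cross.
#' The summaries are smoothed with a width-3 running median (shadows span
#' several columns, so single-column dips are texture, not shadow) and a
#' column is flagged when its summary falls below the B-scan's median by
#' more than `k` MADs *and* by more than the minimum attenuation depth
#' `min_contrast` (a shadow is a multiplicative attenuation of the whole
#' column, so a genuine one dips by a sizeable fraction of the reference
#' level; the contrast floor keeps pure noise excursions below the MAD
#' threshold from being flagged). Flagged columns are dilated by one
#' column each side.
#'
#' @param bscan H x W numeric matrix.
#' @param rpe_curve per-A-scan RPE depth in pixel rows.
#' @param k MAD multiplier for the flag threshold (default 2).
#' @param min_contrast minimum fractional attenuation depth of a genuine
#'   shadow (default 0.05, i.e. the column summary must dip at least 5%
#'   below the B-scan median).
#' @return Logical vector of length W: TRUE = column valid, FALSE =
#'   shadowed. If every column is flagged the scan is unusable and a warning
#'   is emitted (treat as QC-excluded).
#' @export
detect_shadow_columns <- function(bscan, rpe_curve, k = 2,
                                  min_contrast = 0.05) {
  stopifnot(is.matrix(bscan), length(rpe_curve) == ncol(bscan))
  h <- nrow(bscan)
  w <- ncol(bscan)
  m <- vapply(seq_len(w), function(j) {
    lo <- floor(rpe_curve[j]) + 1
    if (lo > h) return(NA_real_)
    mean(bscan[lo:h, j], trim = 0.4)
  }, 0)
  sm <- if (w >= 3) stats::runmed(m, 3, endrule = "median") else m
  med <- stats::median(sm, na.rm = TRUE)
  s <- stats::mad(sm, na.rm = TRUE)
  flag <- !is.na(sm) & sm < med - k * s & sm < (1 - min_contrast) * med
  if (any(flag)) {  # dilate one column each side
    idx <- which(flag)
    flag[pmax(idx - 1L, 1L)] <- TRUE
    flag[pmin(idx + 1L, w)] <- TRUE
  }
  flag[is.na(sm)] <- TRUE
  if (all(flag)) {
    warning("all columns flagged as shadowed; treat this B-scan as QC-excluded",
            call. = FALSE)
  }
  !flag
}

#' Per-A-scan choroidal metrics of one B-scan
#'
#' Choroidal thickness is the real-valued boundary separation converted to
#' um, `ct_um = (csj - rpe) * axial_res_um`; lumen and stroma pixels are
#' counted within the integer band rows. Columns that are shadowed, or
#' whose boundaries are inverted (`csj < rpe`), are invalid and carry no
#' counts.
#'
#' @param bscan H x W numeric matrix.
#' @param rpe_curve,csj_curve per-A-scan boundary rows.
#' @param lumen_mask logical H x W lumen mask from [binarize_choroid()].
#' @param validity logical length-W column validity from
#'   [detect_shadow_columns()] (or all-TRUE).
#' @param axial_res_um um per pixel row.
#' @return A data.frame with one row per A-scan: `ct_um`, `lumen_px`,
#'   `stroma_px`, `valid`, `reason` (`"ok"`, `"shadow"`, or
#'   `"inverted_boundaries"`).
#' @export
compute_column_metrics <- function(bscan, rpe_curve, csj_curve, lumen_mask,
                                   validity = NULL, axial_res_um = 3.9) {
  stopifnot(is.matrix(bscan), is.matrix(lumen_mask),
            all(dim(bscan) == dim(lumen_mask)))
  w <- ncol(bscan)
  h <- nrow(bscan)
  if (is.null(validity)) validity <- rep(TRUE, w)
  stopifnot(length(validity) == w,
            length(rpe_curve) == w, length(csj_curve) == w)
  band <- band_mask(h, rpe_curve, csj_curve)
  lumen_px <- colSums(lumen_mask & band)
  total_px <- colSums(band)
  ct_um <- (csj_curve - rpe_curve) * axial_res_um
  reason <- rep("ok", w)
  valid <- as.logical(validity)
  reason[!valid] <- "shadow"
  inv <- csj_curve < rpe_curve
  valid[inv] <- FALSE
  reason[inv] <- "inverted_boundaries"
  ct_um[inv] <- NA_real_
  lumen_px[!valid] <- NA_integer_
  data.frame(
    ct_um = ct_um,
    lumen_px = ifelse(valid, lumen_px, NA_real_),
    stroma_px = ifelse(valid, total_px - lumen_px, NA_real_),
    valid = valid,
    reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Per-cell choroidal metrics container
#'
#' Four 60x60 matrices of per-cell choroidal thickness (um), luminal and
#' stromal area (um^2) and CVI, plus a validity mask. Invalid cells carry
#' `NA`, never zero. Where valid, `cvi = la / (la + sa)` lies in `[0, 1]`.
#'
#' @param ct_um,la_um2,sa_um2,cvi 60x60 numeric matrices (or `NULL` for a
#'   metric that was not measured).
#' @param valid_mask 60x60 logical matrix.
#' @param cell_size_um cell edge length, um.
#' @return An object of class `cell_metrics_grid`.
#' @export
cell_metrics_grid <- function(ct_um = NULL, la_um2 = NULL, sa_um2 = NULL,
                              cvi = NULL, valid_mask, cell_size_um = 120) {
  as_grid <- function(m, name) {
    if (is.null(m)) return(matrix(NA_real_, 60, 60))
    if (!is.matrix(m) || !all(dim(m) == c(60, 60))) {
      stop(sprintf("'%s' must be a 60x60 matrix", name), call. = FALSE)
    }
    m
  }
  if (!is.matrix(valid_mask) || !all(dim(valid_mask) == c(60, 60))) {
    stop("'valid_mask' must be a 60x60 logical matrix", call. = FALSE)
  }
  structure(
    list(ct_um = as_grid(ct_um, "ct_um"),
         la_um2 = as_grid(la_um2, "la_um2"),
         sa_um2 = as_grid(sa_um2, "sa_um2"),
         cvi = as_grid(cvi, "cvi"),
         valid_mask = valid_mask,
         cell_size_um = cell_size_um),
    class = "cell_metrics_grid"
  )
}

#' @export
print.cell_metrics_grid <- function(x, ...) {
  nv <- sum(x$valid_mask)
  cat(sprintf(
    "<cell_metrics_grid> 60x60 cells (%d valid); median CT %.1f um, CVI %.3f\n",
    nv, stats::median(x$ct_um[x$valid_mask]),
    stats::median(x$cvi[x$valid_mask])))
  invisible(x)
}

#' Aggregate per-column metrics of all B-scans onto the 60x60 grid
#'
#' Every (A-scan, B-scan) sample maps to exactly one fovea-centred grid
#' cell via [grid_index()]. Per cell, CT is the median of valid column CTs
#' (medians are the reporting convention throughout); LA and SA are summed
#' pixel counts scaled by the pixel area, and CVI is computed from the
#' pooled pixel counts, `la / (la + sa)`. A cell is valid iff at least
#' `min_coverage` of its geometrically expected column samples are valid —
#' QC-excluded scans therefore make their rows invalid, not zero.
#'
#' @param column_metrics list with one entry per B-scan of the volume, each
#'   a data.frame from [compute_column_metrics()], or `NULL` for a
#'   QC-excluded scan.
#' @param volume the [oct_volume] the metrics came from.
#' @param min_coverage minimum fraction of expected samples that must be
#'   valid (default 0.5).
#' @return A [cell_metrics_grid].
#' @export
aggregate_to_grid <- function(column_metrics, volume, min_coverage = 0.5) {
  stopifnot(inherits(volume, "oct_volume"),
            length(column_metrics) == length(volume$images))
  n <- length(volume$images)
  w <- ncol(volume$images[[1]])
  x_um <- (seq_len(w) - 0.5) * volume$ascan_spacing_um - volume$fovea_xy_um[["x"]]
  y_um <- (seq_len(n) - 1) * volume$bscan_spacing_um - volume$fovea_xy_um[["y"]]
  gcol <- grid_index(x_um, rep(0, w))$col

  px_area <- volume$ascan_spacing_um * volume$axial_res_um
  expected <- matrix(0L, 60, 60)
  n_valid <- matrix(0L, 60, 60)
  lum <- matrix(0, 60, 60)
  str <- matrix(0, 60, 60)
  ct_vals <- vector("list", 3600L)

  # Warn when the fovea is so off-centre that a substantial part of the
  # grid lies outside the scanned extent (those cells simply stay invalid).
  overlap <- function(lo, hi) max(0, min(hi, 3600) - max(lo, -3600))
  fx <- overlap(min(x_um) - 0.5 * volume$ascan_spacing_um,
                max(x_um) + 0.5 * volume$ascan_spacing_um) / 7200
  fy <- if (n > 1) {
    overlap(min(y_um), max(y_um)) / 7200
  } else {
    1
  }
  if (1 - fx * fy > 0.2) {
    warning("more than 20% of the 7200x7200 um grid falls outside the scanned area; affected cells are invalid",
            call. = FALSE)
  }

  for (s in seq_len(n)) {
    grow <- grid_index(0, y_um[s])$row
    if (is.na(grow)) next
    i <- grow + 1L
    cols <- which(!is.na(gcol))
    key <- gcol[cols] + 1L
    cm <- column_metrics[[s]]
    for (j in sort(unique(key))) {
      sel <- cols[key == j]
      expected[i, j] <- expected[i, j] + length(sel)
      if (is.null(cm)) next
      ok <- sel[cm$valid[sel]]
      if (!length(ok)) next
      n_valid[i, j] <- n_valid[i, j] + length(ok)
      lum[i, j] <- lum[i, j] + sum(cm$lumen_px[ok])
      str[i, j] <- str[i, j] + sum(cm$stroma_px[ok])
      idx <- (j - 1L) * 60L + i
      ct_vals[[idx]] <- c(ct_vals[[idx]], cm$ct_um[ok])
    }
  }

  valid <- expected > 0 & n_valid >= min_coverage * expected
  ct <- matrix(NA_real_, 60, 60)
  ct[valid] <- vapply(which(valid),
                      function(idx) stats::median(ct_vals[[idx]]), 0)
  la <- ifelse(valid, lum * px_area, NA_real_)
  sa <- ifelse(valid, str * px_area, NA_real_)
  denom <- lum + str
  cvi <- ifelse(valid & denom > 0, lum / denom, NA_real_)
  valid <- valid & denom > 0
  la[!valid] <- NA_real_
  sa[!valid] <- NA_real_
  ct[!valid] <- NA_real_
  cell_metrics_grid(ct_um = ct, la_um2 = la, sa_um2 = sa, cvi = cvi,
                    valid_mask = valid)
}

#' Quantify an OCT volume into a 60x60 grid of choroidal metrics
#'
#' Runs the full per-volume pipeline: quality-control filtering
#' ([qc_filter()]), shadow-column detection, multiscale median-cut
#' binarization, per-column metrics, and aggregation onto the fovea-centred
#' 60x60 grid.
#'
#' @param volume an [oct_volume].
#' @param params a [binarization_params()].
#' @param min_quality_db,max_excluded QC thresholds (see [qc_filter()]).
#' @param min_coverage cell validity threshold (see [aggregate_to_grid()]).
#' @param detect_shadows set `FALSE` to skip shadow detection (all columns
#'   valid), e.g. for phantom volumes known to be shadow-free.
#' @return A [cell_metrics_grid]; errors if the QC rejects the volume.
#' @export
quantify_volume <- function(volume, params = binarization_params(),
                            min_quality_db = 15, max_excluded = 2,
                            min_coverage = 0.5, detect_shadows = TRUE) {
  stopifnot(inherits(volume, "oct_volume"))
  qc <- qc_filter(volume, min_quality_db, max_excluded)
  if (!qc$volume_accepted) {
    stop(sprintf("volume rejected by QC: %s", qc$reason), call. = FALSE)
  }
  column_metrics <- vector("list", length(volume$images))
  for (s in seq_along(volume$images)) {
    if (s %in% qc$excluded_bscans) next
    img <- volume$images[[s]]
    rpe <- volume$rpe_curve[s, ]
    csj <- volume$csj_curve[s, ]
    validity <- if (detect_shadows) {
      detect_shadow_columns(img, rpe)
    } else {
      rep(TRUE, ncol(img))
    }
    if (!any(validity)) next  # fully shadowed scan: treated as excluded
    mask <- binarize_choroid(img, rpe, csj, params)
    column_metrics[[s]] <- compute_column_metrics(
      img, rpe, csj, mask, validity, volume$axial_res_um)
  }
  aggregate_to_grid(column_metrics, volume, min_coverage)
}
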