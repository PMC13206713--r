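# Group comparison: difference maps, spatial statistics and eccentricity
# regression models.

#' Symmetric (and raw) percent change between two positive values
#'
#' The symmetric form `100 * (x - c) / ((x + c) / 2)` is bounded in
#' (-200, 200) for positive inputs and antisymmetric under swapping the two
#' groups; it is the default standardization because the raw form
#' `100 * (x - c) / x` is unbounded when the denominator approaches zero.
#'
#' @param x value in the case group (e.g. per-cell group median); positive.
#' @param control value in the control group; positive.
#' @param mode `"symmetric"` (default) or `"raw"`.
#' @return Percent change (vectorised); `NA` where a denominator is not
#'   strictly positive (never infinite).
#' @examples
#' symmetric_percent_change(90, 110)            # -20
#' symmetric_percent_change(90, 110, mode = "raw") # -22.22
#' @export
symmetric_percent_change <- function(x, control, mode = c("symmetric", "raw")) {
  mode <- match.arg(mode)
  out <- if (mode == "symmetric") {
    100 * (x - control) / ((x + control) / 2)
  } else {
    100 * (x - control) / x
  }
  denom_ok <- if (mode == "symmetric") (x + control) > 0 else x > 0
  out[!denom_ok | !is.finite(out)] <- NA_real_
  out
}

#' Per-cell difference map between two groups of eyes
#'
#' For each grid cell, takes the median of the metric over eyes with a valid
#' cell in each group, then the percent change of the case median relative
#' to the control median. A cell is valid iff at least `min_eyes_frac` of
#' the eyes are valid in both groups and both medians are positive.
#'
#' @param iamd,control lists of [cell_metrics_grid] objects (>= 2 eyes each).
#' @param metric one of `"ct"`, `"cvi"`, `"la"`, `"sa"`.
#' @param mode percent-change mode, see [symmetric_percent_change()].
#' @param min_eyes_frac minimum fraction of valid eyes per group per cell.
#' @return An object of class `difference_map`: `values` (60x60 percent
#'   change), `valid_mask`, `metric`, `mode`, `n_iamd`, `n_control`.
#' @export
difference_map <- function(iamd, control, metric = c("cvi", "ct", "la", "sa"),
                           mode = c("symmetric", "raw"),
                           min_eyes_frac = 0.5) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (length(iamd) < 2L || length(control) < 2L) {
    stop("need at least 2 eyes per group", call. = FALSE)
  }
  field <- c(ct = "ct_um", cvi = "cvi", la = "la_um2", sa = "sa_um2")[[metric]]
  group_median <- function(grids) {
    vals <- vapply(grids, function(g) {
      v <- g[[field]]
      v[!g$valid_mask] <- NA_real_
      v
    }, matrix(0, 60, 60))
    med <- apply(vals, c(1, 2), stats::median, na.rm = TRUE)
    n_ok <- apply(!is.na(vals), c(1, 2), sum)
    list(median = med, n_ok = n_ok)
  }
  gi <- group_median(iamd)
  gc <- group_median(control)
  valid <- gi$n_ok >= min_eyes_frac * length(iamd) &
    gc$n_ok >= min_eyes_frac * length(control) &
    is.finite(gi$median) & is.finite(gc$median) &
    gi$median > 0 & gc$median > 0
  values <- matrix(NA_real_, 60, 60)
  values[valid] <- symmetric_percent_change(gi$median[valid],
                                            gc$median[valid], mode)
  valid <- valid & !is.na(values)
  if (!any(valid)) {
    warning("difference map has no valid cells", call. = FALSE)
  }
  structure(
    list(values = values, valid_mask = valid, metric = metric, mode = mode,
         n_iamd = length(iamd), n_control = length(control)),
    class = "difference_map"
  )
}

#' @export
print.difference_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf(
    "<difference_map> %s (%s), %d vs %d eyes; %d valid cells; median %+.2f%%\n",
    toupper(x$metric), x$mode, x$n_iamd, x$n_control, length(v),
    stats::median(v)))
  invisible(x)
}

# Paired Wilcoxon signed-rank with the documented conventions: zero
# differences dropped first, exact distribution for n <= 25 afterwards.
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) {
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = length(d) <= 25, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_used = length(d))
}

#' Global comparison of a choroidal metric between two groups
#'
#' Each eye is summarised by the median of its metric over valid cells;
#' matched groups are compared with the Wilcoxon signed-rank test (zero
#' differences dropped, exact distribution for n <= 25 pairs). The median
#' and interquartile range of the per-pair symmetric percent changes are
#' reported alongside. If the groups are unmatched in size the comparison
#' falls back to the rank-sum (Mann-Whitney) test, with a warning recorded
#' in the output.
#'
#' @inheritParams difference_map
#' @param paired compare eyes pairwise by index (default) or as independent
#'   samples.
#' @return A list: `statistic`, `p_value`, `median_diff` (%), `iqr`
#'   (length-2), `test` (`"signed_rank"` or `"rank_sum"`), `n`.
#' @export
global_compare <- function(iamd, control, metric = c("cvi", "ct", "la", "sa"),
                           mode = c("symmetric", "raw"), paired = TRUE) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  field <- c(ct = "ct_um", cvi = "cvi", la = "la_um2", sa = "sa_um2")[[metric]]
  eye_global <- function(g) {
    v <- g[[field]][g$valid_mask]
    stats::median(v[is.finite(v)])
  }
  xi <- vapply(iamd, eye_global, 0)
  xc <- vapply(control, eye_global, 0)
  test <- "signed_rank"
  if (paired && length(xi) != length(xc)) {
    warning("groups are not matched 1:1; falling back to the rank-sum test",
            call. = FALSE)
    paired <- FALSE
  }
  if (paired) {
    ht <- wilcoxon_signed_rank(xi, xc)
    statistic <- ht$statistic
    p <- ht$p_value
    pc <- symmetric_percent_change(xi, xc, mode)
  } else {
    test <- "rank_sum"
    ht <- suppressWarnings(
      stats::wilcox.test(xi, xc, exact = length(xi) + length(xc) <= 50))
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    pc <- symmetric_percent_change(xi, stats::median(xc), mode)
  }
  list(
    statistic = statistic,
    p_value = p,
    median_diff = stats::median(pc, na.rm = TRUE),
    iqr = unname(stats::quantile(pc, c(0.25, 0.75), na.rm = TRUE)),
    test = test,
    n = c(iamd = length(xi), control = length(xc))
  )
}

#' Sectoral statistics of a difference map
#'
#' Two complementary analyses on the per-cell percent-change values:
#' (i) a Kruskal-Wallis test across the four ETDRS rings (central, inner,
#' outer, near periphery), asking whether the change differs by ring; and
#' (ii) a one-sample Wilcoxon signed-rank test of each of the 13 sectors
#' against zero, Holm-corrected across sectors. Sectors with fewer than
#' `min_cells` valid cells are excluded and flagged.
#'
#' @param diff_map a [difference_map].
#' @param laterality eye laterality for the sector template.
#' @param min_cells minimum valid cells for a sector to be tested.
#' @return A list: `ring_test` (statistic, df, p_value), `sector_table`
#'   (data.frame with median, IQR, statistic, p, Holm-corrected p and an
#'   `excluded` flag per sector).
#' @export
sector_compare <- function(diff_map, laterality = c("OD", "OS"),
                           min_cells = 5) {
  stopifnot(inherits(diff_map, "difference_map"))
  laterality <- match.arg(laterality)
  tmpl <- etdrs_template(laterality)
  vals <- diff_map$values
  ok <- diff_map$valid_mask
  if (!any(ok)) stop("difference map has no valid cells", call. = FALSE)

  ring <- sub("_(superior|nasal|inferior|temporal)$", "", tmpl)
  rv <- vals[ok]
  rg <- factor(ring[ok],
               levels = c("central", "inner", "outer", "near_periphery"))
  ring_test <- if (length(unique(rv)) <= 1L) {
    # all values identical: no evidence of ring differences by convention
    list(statistic = 0, df = nlevels(droplevels(rg)) - 1L, p_value = 1)
  } else {
    ht <- stats::kruskal.test(rv, rg)
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
  }

  sectors <- etdrs_sector_levels()
  rows <- lapply(sectors, function(s) {
    v <- vals[ok & tmpl == s]
    if (length(v) < min_cells) {
      return(data.frame(sector = s, n_cells = length(v), median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_, statistic = NA_real_,
                        p_value = NA_real_, excluded = TRUE))
    }
    nz <- v[v != 0]
    if (!length(nz)) {
      st <- NA_real_
      p <- 1
    } else {
      ht <- suppressWarnings(
        stats::wilcox.test(nz, mu = 0, exact = length(nz) <= 25))
      st <- unname(ht$statistic)
      p <- ht$p.value
    }
    data.frame(sector = s, n_cells = length(v),
               median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               statistic = st, p_value = p, excluded = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_holm <- NA_real_
  tested <- !tab$excluded
  tab$p_holm[tested] <- stats::p.adjust(tab$p_value[tested], method = "holm")
  list(ring_test = ring_test, sector_table = tab)
}

#' Linear and quadratic eccentricity models of a difference map
#'
#' Bins the valid cells by eccentricity of their centres (half-open bins of
#' `bin_width_mm`), takes the median cell value per bin, and fits ordinary
#' least squares polynomials of degree 1 and 2 to the bin medians against
#' the bin centres. Both fits are reported; the chosen model is the
#' quadratic only when its R-squared exceeds the linear one by more than
#' `r2_tol` (the nested quadratic never has lower R-squared, so a tolerance
#' is required to prefer the simpler model on ties). Bins are equally
#' weighted.
#'
#' @param diff_map a [difference_map].
#' @param bin_width_mm eccentricity bin width (default 0.05 mm).
#' @param fit_range_mm length-2 eccentricity range of bins entering the fit.
#' @param r2_tol minimum R-squared gain for the quadratic to be chosen.
#' @return An object of class `eccentricity_fit`; see [eccentricity_fit()].
#' @export
fit_eccentricity_model <- function(diff_map, bin_width_mm = 0.05,
                                   fit_range_mm = c(0, 3), r2_tol = 0.01) {
  stopifnot(inherits(diff_map, "difference_map"))
  cc <- grid_cell_centers()
  ok <- diff_map$valid_mask
  r <- cc$r_mm[ok]
  v <- diff_map$values[ok]
  keep <- r >= fit_range_mm[1] & r < fit_range_mm[2]
  r <- r[keep]
  v <- v[keep]
  if (!length(r)) stop("no valid cells in the fit range", call. = FALSE)
  bin <- eccentricity_bin(r, bin_width_mm)
  med <- tapply(v, bin, stats::median)
  centers <- (as.numeric(names(med)) + 0.5) * bin_width_mm
  fit_bins(centers, as.numeric(med), fit_range_mm, r2_tol)
}

# Fit degree-1 and degree-2 OLS models to binned responses; shared by
# fit_eccentricity_model() and direct use on externally binned data.
fit_bins <- function(x, y, fit_range_mm, r2_tol = 0.01) {
  n <- length(x)
  if (n < 3L) {
    stop("fewer populated bins than linear model parameters; fit omitted",
         call. = FALSE)
  }
  r2_of <- function(fit) {
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) return(0)      # zero-variance response: R^2 = 0
    1 - sum(stats::residuals(fit)^2) / ss_tot
  }
  lin <- stats::lm(y ~ x)
  lin_coef <- c(m = unname(stats::coef(lin)[2]),
                k = unname(stats::coef(lin)[1]))
  lin_r2 <- r2_of(lin)
  quad <- NULL
  quad_coef <- c(a = NA_real_, b = NA_real_, c = NA_real_)
  quad_r2 <- NA_real_
  if (n >= 4L) {
    quad <- stats::lm(y ~ x + I(x^2))
    quad_coef <- c(a = unname(stats::coef(quad)[3]),
                   b = unname(stats::coef(quad)[2]),
                   c = unname(stats::coef(quad)[1]))
    quad_r2 <- r2_of(quad)
  }
  chosen <- if (!is.null(quad) && is.finite(quad_r2) &&
                quad_r2 > lin_r2 + r2_tol) "quadratic" else "linear"
  model <- if (chosen == "quadratic") quad else lin
  # perfect fits (exact polynomial bins) make summary.lm warn; that case is
  # legitimate here
  fstat <- suppressWarnings(summary(model)$fstatistic)
  p <- if (is.null(fstat)) {
    NA_real_
  } else {
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  }
  eccentricity_fit(
    linear = lin_coef, quadratic = quad_coef,
    linear_r2 = lin_r2, quadratic_r2 = quad_r2,
    chosen = chosen, p_value = p, fit_range_mm = fit_range_mm,
    n_bins = n
  )
}

#' Eccentricity model fit container
#'
#' Holds the linear (`y = m*x + k`) and quadratic (`y = a*x^2 + b*x + c`)
#' least-squares fits of a percent-change response against eccentricity
#' (mm), their R-squared values, and which model was selected. Can also be
#' constructed directly from published coefficients to interrogate model
#' features.
#'
#' @param linear named numeric `c(m, k)`.
#' @param quadratic named numeric `c(a, b, c)` (may be `NA` if not fitted).
#' @param linear_r2,quadratic_r2 R-squared of each fit.
#' @param chosen `"linear"` or `"quadratic"`.
#' @param p_value overall F-test p-value of the chosen model.
#' @param fit_range_mm eccentricity range the fit covers.
#' @param n_bins number of bins entering the fit.
#' @return An object of class `eccentricity_fit`.
#' @export
eccentricity_fit <- function(linear = c(m = NA_real_, k = NA_real_),
                             quadratic = c(a = NA_real_, b = NA_real_,
                                           c = NA_real_),
                             linear_r2 = NA_real_, quadratic_r2 = NA_real_,
                             chosen = c("linear", "quadratic"),
                             p_value = NA_real_, fit_range_mm = c(0, 3),
                             n_bins = NA_integer_) {
  chosen <- match.arg(chosen)
  linear <- stats::setNames(as.numeric(linear), c("m", "k"))
  quadratic <- stats::setNames(as.numeric(quadratic), c("a", "b", "c"))
  structure(
    list(linear = linear, quadratic = quadratic,
         linear_r2 = linear_r2, quadratic_r2 = quadratic_r2,
         chosen = chosen, p_value = p_value,
         fit_range_mm = fit_range_mm, n_bins = n_bins),
    class = "eccentricity_fit"
  )
}

#' @export
print.eccentricity_fit <- function(x, ...) {
  cat("<eccentricity_fit>\n")
  cat(sprintf("  linear:    y = %.4f x + %.4f   (R2 = %.4f)\n",
              x$linear[["m"]], x$linear[["k"]], x$linear_r2))
  if (is.finite(x$quadratic[["a"]])) {
    cat(sprintf("  quadratic: y = %.4f x^2 + %.4f x + %.4f   (R2 = %.4f)\n",
                x$quadratic[["a"]], x$quadratic[["b"]], x$quadratic[["c"]],
                x$quadratic_r2))
  }
  cat(sprintf("  chosen: %s; p = %s; bins = %s\n", x$chosen,
              format(x$p_value), x$n_bins))
  invisible(x)
}

#' Geometric features of a fitted eccentricity model
#'
#' For the chosen linear model, the sign-change eccentricity (x-intercept)
#' `-k/m`; for the chosen quadratic, the vertex `-b/(2a)`, its extremal
#' value, and any real roots within the fit range. Features are computed at
#' full precision; `reported` rounds them to one decimal mm for
#' presentation, which is the only place rounding happens.
#'
#' @param fit an [eccentricity_fit].
#' @return A list with `model`, the full-precision features (`root_mm` or
#'   `vertex_mm` / `extremum_value` / `roots_mm`), and `reported`, the same
#'   rounded to 1 decimal. Degenerate leading coefficients give absent
#'   (`NULL`-omitted, `NA`) features.
#' @export
model_features <- function(fit) {
  stopifnot(inherits(fit, "eccentricity_fit"))
  if (fit$chosen == "linear") {
    m <- fit$linear[["m"]]
    k <- fit$linear[["k"]]
    root <- if (is.finite(m) && m != 0) -k / m else NA_real_
    return(list(model = "linear", root_mm = root,
                reported = list(root_mm = round(root, 1))))
  }
  a <- fit$quadratic[["a"]]
  b <- fit$quadratic[["b"]]
  cc <- fit$quadratic[["c"]]
  if (!is.finite(a) || a == 0) {
    return(list(model = "quadratic", vertex_mm = NA_real_,
                extremum_value = NA_real_, roots_mm = numeric(0),
                reported = list(vertex_mm = NA_real_)))
  }
  vertex <- -b / (2 * a)
  extremum <- a * vertex^2 + b * vertex + cc
  disc <- b^2 - 4 * a * cc
  roots <- if (disc >= 0) {
    sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  } else {
    numeric(0)
  }
  roots <- roots[roots >= fit$fit_range_mm[1] & roots <= fit$fit_range_mm[2]]
  list(model = "quadratic", vertex_mm = vertex, extremum_value = extremum,
       roots_mm = roots,
       reported = list(vertex_mm = round(vertex, 1),
                       extremum_value = round(extremum, 1),
                       roots_mm = round(roots, 1)))
}

#' Spearman correlation between two difference maps
#'
#' Rank correlation either of the per-bin median profiles (default,
#' matching how eccentricity results are presented) or of the raw per-cell
#' values, over cells/bins valid in both maps.
#'
#' @param map_a,map_b [difference_map] objects on the same grid.
#' @param level `"bin"` (per-eccentricity-bin medians) or `"cell"`.
#' @param bin_width_mm bin width for `level = "bin"`.
#' @return A list: `rho`, `p_value`, `n` (shared points).
#' @export
correlate_metrics <- function(map_a, map_b, level = c("bin", "cell"),
                              bin_width_mm = 0.05) {
  stopifnot(inherits(map_a, "difference_map"),
            inherits(map_b, "difference_map"))
  level <- match.arg(level)
  ok <- map_a$valid_mask & map_b$valid_mask
  va <- map_a$values[ok]
  vb <- map_b$values[ok]
  if (level == "bin") {
    cc <- grid_cell_centers()
    bin <- eccentricity_bin(cc$r_mm[ok], bin_width_mm)
    va <- as.numeric(tapply(va, bin, stats::median))
    vb <- as.numeric(tapply(vb, bin, stats::median))
  }
  if (length(va) < 3L) {
    stop("need at least 3 shared points for a correlation", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::cor.test(va, vb, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(va))
}

#' Shapiro-Wilk normality check
#'
#' Used to justify the nonparametric (median/IQR, rank-based) reporting;
#' the choice of test is never switched silently on its outcome.
#'
#' @param values numeric vector, 3 <= n <= 5000, not all identical.
#' @return A list: `W`, `p_value`, `n`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 finite values", call. = FALSE)
  }
  if (diff(range(values)) == 0) {
    stop("normality check undefined for a constant vector", call. = FALSE)
  }
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p_value = ht$p.value, n = n)
}
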