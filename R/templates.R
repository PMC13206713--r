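#' Map fovea-centred positions to 60x60 grid cells
#'
#' The analysis grid is a fovea-centred 60x60 lattice of 120-um cells
#' covering 7200 x 7200 um. Cells are half-open: a coordinate `v` in
#' `[-3600, 3600)` um maps to index `floor((v + 3600) / 120)` (0-based).
#' Rows index the vertical (inter-B-scan) axis, columns the horizontal
#' (A-scan) axis.
#'
#' @param x_um,y_um numeric vectors of fovea-centred coordinates in um.
#' @return A list with integer vectors `row` and `col` (0-based); coordinates
#'   outside the grid give `NA` ("outside grid" sentinel).
#' @examples
#' grid_index(0, 0)        # cell (30, 30)
#' grid_index(-3600, -3600) # cell (0, 0)
#' @export
grid_index <- function(x_um, y_um) {
  stopifnot(length(x_um) == length(y_um))
  col <- floor((x_um + 3600) / 120)
  row <- floor((y_um + 3600) / 120)
  col[col < 0 | col > 59] <- NA_integer_
  row[row < 0 | row > 59] <- NA_integer_
  out <- is.na(col) | is.na(row)
  col[out] <- NA_integer_
  row[out] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Fovea-centred coordinates of the 60x60 grid-cell centres
#'
#' @return A list of two 60x60 matrices `x_um` and `y_um` (centre of cell
#'   `[i, j]` at row i, column j, 1-based), plus `r_mm`, the eccentricity of
#'   each cell centre in mm.
#' @export
grid_cell_centers <- function() {
  centers <- -3600 + (seq_len(60) - 0.5) * 120
  x <- matrix(centers, nrow = 60, ncol = 60, byrow = TRUE)
  y <- matrix(centers, nrow = 60, ncol = 60)
  list(x_um = x, y_um = y, r_mm = sqrt(x^2 + y^2) / 1000)
}

#' ETDRS sector of a fovea-centred position
#'
#' Assigns Early Treatment Diabetic Retinopathy Study (ETDRS) sector labels
#' extended with a near-periphery ring: rings are half-open annuli of radius
#' `[0, 500)`, `[500, 1500)`, `[1500, 3000)` and `[3000, Inf)` um
#' (1-, 3- and 6-mm diameter circles); the three outer rings are split into
#' superior / nasal / inferior / temporal quadrants at the 45-degree
#' diagonals. The central disc carries no quadrant. For left eyes (OS) the
#' nasal/temporal assignment is mirrored about the vertical axis so labels
#' are anatomic: `etdrs_sector(x, y, "OD")` and `etdrs_sector(-x, y, "OS")`
#' agree everywhere. Points exactly on a diagonal boundary join the
#' horizontal (nasal or temporal) quadrant, which preserves that mirror
#' symmetry.
#'
#' @param x_um,y_um fovea-centred coordinates in um; positive `y` is
#'   superior; positive `x` is nasal for OD and temporal for OS.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @return A character vector of sector labels such as `"central"`,
#'   `"inner_superior"`, `"outer_temporal"`, `"near_periphery_nasal"`.
#' @export
etdrs_sector <- function(x_um, y_um, laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  stopifnot(length(x_um) == length(y_um))
  r <- sqrt(x_um^2 + y_um^2)
  ring <- cut(r, c(0, 500, 1500, 3000, Inf),
              labels = c("central", "inner", "outer", "near_periphery"),
              right = FALSE, include.lowest = TRUE)
  # Horizontal quadrants absorb the |x| == |y| boundary (mirror-symmetric).
  quad <- ifelse(abs(y_um) > abs(x_um),
                 ifelse(y_um > 0, "superior", "inferior"),
                 ifelse(x_um >= 0, "right", "left"))
  horiz <- if (laterality == "OD") c(right = "nasal", left = "temporal") else
    c(right = "temporal", left = "nasal")
  quad[quad == "right"] <- horiz[["right"]]
  quad[quad == "left"] <- horiz[["left"]]
  out <- ifelse(ring == "central", "central", paste(ring, quad, sep = "_"))
  out[r == 0] <- "central"
  as.character(out)
}

#' All 13 realizable ETDRS sector labels
#' @return Character vector: central plus four quadrants in each of the
#'   inner, outer and near-periphery rings.
#' @export
etdrs_sector_levels <- function() {
  quads <- c("superior", "nasal", "inferior", "temporal")
  c("central",
    paste("inner", quads, sep = "_"),
    paste("outer", quads, sep = "_"),
    paste("near_periphery", quads, sep = "_"))
}

#' 60x60 template of ETDRS sector labels at cell centres
#'
#' @inheritParams etdrs_sector
#' @return A 60x60 character matrix of sector labels.
#' @export
etdrs_template <- function(laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  cc <- grid_cell_centers()
  matrix(etdrs_sector(as.vector(cc$x_um), as.vector(cc$y_um), laterality),
         nrow = 60, ncol = 60)
}

#' Eccentricity bin of a radial distance
#'
#' Half-open radial bins of fixed width (default 0.05 mm, matching the grid
#' resolution): `r` in `[i*w, (i+1)*w)` maps to bin `i` (0-based). The bin
#' centre `(i + 0.5) * w` is used as the regression abscissa in
#' [fit_eccentricity_model()].
#'
#' @param r_mm nonnegative eccentricity in mm.
#' @param width_mm bin width in mm.
#' @return Integer vector of 0-based bin indices.
#' @examples
#' eccentricity_bin(0.12) # bin 2
#' @export
eccentricity_bin <- function(r_mm, width_mm = 0.05) {
  stopifnot_scalar(width_mm, "width_mm", lo = 1e-6)
  if (any(!is.finite(r_mm)) || any(r_mm < 0)) {
    stop("eccentricity must be finite and nonnegative", call. = FALSE)
  }
  as.integer(floor(r_mm / width_mm))
}

#' 60x60 template of eccentricity bin indices at cell centres
#'
#' @inheritParams eccentricity_bin
#' @return A 60x60 integer matrix of 0-based bin indices.
#' @export
eccentricity_template <- function(width_mm = 0.05) {
  cc <- grid_cell_centers()
  matrix(eccentricity_bin(as.vector(cc$r_mm), width_mm), nrow = 60, ncol = 60)
}
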