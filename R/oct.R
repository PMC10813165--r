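# ETDRS sector analysis of segmented OCT layer-thickness maps: mean
# thickness over the outer-ring (3-6 mm) annulus quadrants centred on
# the optic nerve head.

#' Segmented layer-thickness map
#'
#' @param grid Numeric matrix of thickness (um); rows index the vertical
#'   image axis (row 1 = superior edge), columns the horizontal axis.
#'   Missing pixels are NA.
#' @param pitch_mm Length-2 physical pixel pitch `(x, y)` in mm/pixel.
#' @param centre_px Length-2 real-valued optic-nerve-head position
#'   `(row, col)` in pixel coordinates.
#' @param layer Layer label (RNFL, GCIPL, INL, OPL, ONL, TRT).
#' @param eye "OD" (right) or "OS" (left); determines the nasal/temporal
#'   quadrant assignment.
#' @return An object of class `thickness_map`.
#' @export
thickness_map <- function(grid, pitch_mm, centre_px = (dim(grid) + 1) / 2,
                          layer = "TRT", eye = c("OD", "OS")) {
  eye <- match.arg(eye)
  stopifnot(is.matrix(grid), is.numeric(grid))
  if (length(pitch_mm) == 1) pitch_mm <- rep(pitch_mm, 2)
  stopifnot(length(pitch_mm) == 2, all(pitch_mm > 0),
            length(centre_px) == 2)
  if (any(grid < 0, na.rm = TRUE)) stop("thickness must be >= 0 or NA")
  structure(list(grid = grid, pitch_mm = as.numeric(pitch_mm),
                 centre_px = as.numeric(centre_px), layer = layer, eye = eye),
            class = "thickness_map")
}

# physical (x, y) coordinates (mm) of every pixel relative to the centre;
# +y is superior (row index decreases upward), +x is the right of the image
map_coords <- function(m) {
  nr <- nrow(m$grid); nc <- ncol(m$grid)
  x <- (matrix(rep(seq_len(nc), each = nr), nr, nc) - m$centre_px[2]) * m$pitch_mm[1]
  y <- (m$centre_px[1] - matrix(rep(seq_len(nr), nc), nr, nc)) * m$pitch_mm[2]
  list(x = x, y = y)
}

#' ETDRS outer-ring quadrant mean thicknesses
#'
#' Averages map pixels over the four quadrants of the ETDRS outer ring.
#' A pixel belongs to the outer ring iff
#' `ring_mm[2]/2 <= dist(pixel, centre) < ring_mm[3]/2` in physical
#' units (half-open interval, so ring-boundary pixels are never counted
#' twice). Quadrants are delimited by the 45-degree diagonals: superior
#' is polar angle [45, 135), inferior [225, 315); the two horizontal
#' quadrants are labelled nasal/temporal according to the eye side
#' (OD: temporal = angle in [-45, 45), nasal = [135, 225); OS mirrored).
#' NA pixels are ignored by the means; per-quadrant coverage is the
#' fraction of non-NA ring pixels.
#'
#' @param m A [thickness_map()].
#' @param ring_mm ETDRS diameters `(inner_exclusion, ring_inner,
#'   ring_outer)` in mm, default `c(1, 3, 6)`.
#' @param min_coverage Quadrants with coverage below this are flagged.
#' @return An object of class `etdrs_sectors`: quadrant means (um),
#'   pixel-count-weighted combined outer-ring mean, coverage per
#'   quadrant, low-coverage flag.
#' @export
etdrs_quadrant_means <- function(m, ring_mm = c(1, 3, 6), min_coverage = 0.5) {
  stopifnot(inherits(m, "thickness_map"), length(ring_mm) == 3,
            all(diff(ring_mm) > 0), all(ring_mm > 0))
  co <- map_coords(m)
  r <- sqrt(co$x^2 + co$y^2)
  ring <- r >= ring_mm[2] / 2 & r < ring_mm[3] / 2
  if (!any(ring)) stop("the outer-ring annulus does not intersect the map")
  ang <- atan2(co$y, co$x) * 180 / pi          # (-180, 180], 0 = +x axis
  quad <- matrix(NA_character_, nrow(r), ncol(r))
  quad[ang >= 45 & ang < 135] <- "superior"
  quad[ang >= -135 & ang < -45] <- "inferior"
  right <- ang >= -45 & ang < 45
  left <- is.na(quad) & !right
  if (m$eye == "OD") {
    quad[right] <- "temporal"; quad[left] <- "nasal"
  } else {
    quad[right] <- "nasal"; quad[left] <- "temporal"
  }
  qnames <- c("superior", "inferior", "nasal", "temporal")
  means <- cover <- counts <- stats::setNames(numeric(4), qnames)
  for (q in qnames) {
    sel <- ring & quad == q
    tot <- sum(sel)
    val <- m$grid[sel]
    ok <- !is.na(val)
    counts[q] <- sum(ok)
    cover[q] <- if (tot > 0) sum(ok) / tot else 0
    means[q] <- if (sum(ok) > 0) mean(val[ok]) else NA_real_
  }
  combined <- sum(means * counts, na.rm = TRUE) / sum(counts[!is.na(means)])
  structure(list(quadrant_means_um = means,
                 combined_mean_um = combined,
                 coverage = cover,
                 n_pixels = counts,
                 ring_mm = ring_mm, eye = m$eye, layer = m$layer,
                 low_coverage = any(cover < min_coverage)),
            class = "etdrs_sectors")
}

#' @export
print.etdrs_sectors <- function(x, ...) {
  cat(sprintf("<etdrs_sectors> %s (%s), outer ring %g-%g mm\n", x$layer, x$eye,
              x$ring_mm[2], x$ring_mm[3]))
  cat(sprintf("  combined %.2f um | %s%s\n", x$combined_mean_um,
              paste(sprintf("%s %.2f", names(x$quadrant_means_um),
                            x$quadrant_means_um), collapse = ", "),
              if (x$low_coverage) " [LOW COVERAGE]" else ""))
  invisible(x)
}

#' Build a longitudinal measure table from thickness maps
#'
#' Computes the combined outer-ring mean of each map and assembles one
#' row per subject x time x layer, ready for the longitudinal
#' statistics. Alternatively accepts pre-sectored thickness values.
#'
#' @param maps List of [thickness_map()] objects, parallel to `metadata`
#'   rows; or NULL when `values_um` is supplied.
#' @param metadata data.frame with columns subject, genotype, treatment,
#'   time_min (one row per map or value).
#' @param values_um Optional numeric vector of pre-sectored thickness
#'   values (used instead of `maps`); `metadata` must then also carry a
#'   `layer` column.
#' @param ring_mm ETDRS ring diameters passed to
#'   [etdrs_quadrant_means()].
#' @return Measure table data.frame: subject, genotype, treatment,
#'   time_min, measure (= layer), value (um).
#' @export
oct_measure_table <- function(maps = NULL, metadata, values_um = NULL,
                              ring_mm = c(1, 3, 6)) {
  stopifnot(is.data.frame(metadata), nrow(metadata) > 0,
            all(c("subject", "genotype", "treatment", "time_min") %in% names(metadata)))
  if (is.null(maps) && is.null(values_um)) stop("supply maps or values_um")
  if (!is.null(values_um)) {
    stopifnot(length(values_um) == nrow(metadata), "layer" %in% names(metadata))
    layer <- metadata$layer
    value <- as.numeric(values_um)
  } else {
    stopifnot(is.list(maps), length(maps) == nrow(metadata))
    sect <- lapply(maps, etdrs_quadrant_means, ring_mm = ring_mm)
    layer <- vapply(maps, function(m) m$layer, character(1))
    value <- vapply(sect, function(s) s$combined_mean_um, numeric(1))
  }
  out <- data.frame(subject = metadata$subject, genotype = metadata$genotype,
                    treatment = metadata$treatment, time_min = metadata$time_min,
                    measure = layer, value = value, stringsAsFactors = FALSE)
  out$group <- paste(out$genotype, out$treatment, sep = "_")
  key <- paste(out$subject, out$time_min, out$measure)
  if (anyDuplicated(key))
    stop("duplicate subject/time/layer records: ", key[duplicated(key)][1])
  out
}

#' Simulate a smooth random thickness map
#'
#' A base thickness plus a low-order smooth spatial field and pixel
#' noise; useful for exercising the sector pipeline end to end.
#'
#' @param n_px Map side length in pixels (square map).
#' @param pitch_mm Pixel pitch (mm).
#' @param base_um Base thickness.
#' @param ampl_um Amplitude of the smooth spatial variation.
#' @param noise_sd_um Pixel noise SD.
#' @param layer,eye Passed to [thickness_map()].
#' @param seed Integer seed.
#' @return A [thickness_map()].
#' @export
simulate_thickness_map <- function(n_px = 81, pitch_mm = 0.1, base_um = 220,
                                   ampl_um = 10, noise_sd_um = 2,
                                   layer = "TRT", eye = "OD", seed = 1) {
  with_seed(seed, {
    cx <- (n_px + 1) / 2
    x <- (seq_len(n_px) - cx) * pitch_mm
    a <- stats::rnorm(5)
    fld <- outer(x, x, function(yy, xx)
      base_um + ampl_um * (a[1] * sin(xx / 2) + a[2] * cos(yy / 2) +
                             a[3] * xx * yy / 10 + a[4] * sin(xx * yy / 5) +
                             a[5] * cos((xx + yy) / 3)))
    fld <- fld + matrix(stats::rnorm(n_px^2, 0, noise_sd_um), n_px, n_px)
    fld[fld < 0] <- 0
    thickness_map(fld, pitch_mm = pitch_mm, layer = layer, eye = eye)
  })
}
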