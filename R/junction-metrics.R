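# Line- and region-based junctional staining quantifications: the junctional
# formation index (JFI), tricellular accumulation, apical/basal F-actin
# ratio, and background-corrected integrated densities of junctional
# segments.

#' Junctional formation index
#'
#' Ratio of the mean fluorescence intensity along a junctional line to the
#' average of the mean intensities of two parallel cytosolic lines:
#' `jfi = mean(junction) / ((mean(cytosol_a) + mean(cytosol_b)) / 2)`.
#' Values near 1 indicate no junctional enrichment; a fully formed junction
#' scores the junction-to-cytosol contrast of the stain. Conventional stroke
#' widths are 15 px for occludin-type channels and 20 px for
#' p120-catenin-type channels (set them on the ROIs via
#' [default_stroke_width()]).
#'
#' @param image An [intensity_image()].
#' @param junction,cytosol_a,cytosol_b [roi_line()] ROIs within the image.
#' @return One-row tibble: `jfi`, the three means and the stroke width.
#' @export
junction_formation_index <- function(image, junction, cytosol_a, cytosol_b) {
  mj <- mean_intensity_along(image, junction)
  ma <- mean_intensity_along(image, cytosol_a)
  mb <- mean_intensity_along(image, cytosol_b)
  denom <- (ma + mb) / 2
  if (denom <= 0) {
    stop("undefined ratio: cytosolic mean intensity is zero", call. = FALSE)
  }
  tibble::tibble(jfi = mj / denom, junction_mean = mj, cytosol_mean_a = ma,
                 cytosol_mean_b = mb, width_px = junction$width_px)
}

#' Conventional stroke width for a channel type
#'
#' @param channel_type `"occludin"` (15 px) or `"p120"` (20 px).
#' @return Stroke width in pixels.
#' @export
default_stroke_width <- function(channel_type = c("occludin", "p120")) {
  switch(match.arg(channel_type), occludin = 15, p120 = 20)
}

# Histogram mode over the lowest 90% of intensities: a robust, deterministic
# background estimate for integrated densities.
background_mode <- function(pixels, upper_quantile = 0.9, n_bins = 256L) {
  v <- as.vector(pixels)
  cut_hi <- stats::quantile(v, upper_quantile, names = FALSE)
  v <- v[v <= cut_hi]
  if (length(unique(v)) == 1L) return(v[1])
  h <- graphics::hist(v, breaks = n_bins, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Tricellular accumulation ratio
#'
#' Mean integrated density (background-subtracted mean intensity times ROI
#' area) of a tricellular-corner ROI normalised by that of the ROI covering
#' the whole cell. The background is the image histogram mode over the
#' lowest 90% of values.
#'
#' @param image An [intensity_image()].
#' @param corner_roi,cell_roi [roi_region()] polygons; the corner should lie
#'   within the cell ROI.
#' @return One-row tibble: `ratio`, the two integrated densities, areas in
#'   px² and the background estimate.
#' @export
tricellular_accumulation <- function(image, corner_roi, cell_roi) {
  bg <- background_mode(image$pixels)
  mid <- function(roi) {
    mask <- polygon_mask(dim(image$pixels), roi)
    if (!any(mask)) stop("ROI lies outside the image", call. = FALSE)
    area <- sum(mask)
    m <- max(mean(image$pixels[mask]) - bg, 0)
    c(density = m * area, area = area)
  }
  corner <- mid(corner_roi); cell <- mid(cell_roi)
  if (cell["density"] <= 0) {
    stop("undefined ratio: cell ROI integrated density is zero", call. = FALSE)
  }
  tibble::tibble(ratio = corner[["density"]] / cell[["density"]],
                 corner_density = corner[["density"]],
                 cell_density = cell[["density"]],
                 corner_area_px2 = corner[["area"]],
                 cell_area_px2 = cell[["area"]], background = bg)
}

#' Apical over basal mean intensity ratio
#'
#' For a vertical (xz) section: ratio of the mean intensity inside a
#' manually outlined apical region to that of a basal region, one value per
#' cell.
#'
#' @param xz_image An [intensity_image()] of the vertical section.
#' @param apical_roi,basal_roi [roi_region()] outlines.
#' @return One-row tibble: `ratio`, `apical_mean`, `basal_mean`.
#' @export
apical_basal_ratio <- function(xz_image, apical_roi, basal_roi) {
  mroi <- function(roi) {
    mask <- polygon_mask(dim(xz_image$pixels), roi)
    if (!any(mask)) stop("ROI lies outside the image", call. = FALSE)
    mean(xz_image$pixels[mask])
  }
  ap <- mroi(apical_roi); ba <- mroi(basal_roi)
  if (ba <= 0) stop("undefined ratio: basal mean is zero", call. = FALSE)
  tibble::tibble(ratio = ap / ba, apical_mean = ap, basal_mean = ba)
}

#' Background-corrected integrated densities of junctional segments
#'
#' For each line segment, `(mean within stroke - background)` clipped at
#' zero, multiplied by the stroke area in pixels. Used on FRET efficiency
#' maps and on any intensity channel.
#'
#' @param map An [intensity_image()] or `efficiency_map`.
#' @param segments List of [roi_line()] segments.
#' @param background Scalar background level (>= 0); defaults to the image
#'   histogram mode.
#' @return Tibble with one row per segment: `segment`, `mean`,
#'   `area_px2`, `integrated_density`.
#' @export
junctional_segment_value <- function(map, segments, background = NULL) {
  pixels <- map$pixels
  if (is.null(background)) background <- background_mode(pixels[is.finite(pixels)])
  if (background < 0) stop("`background` must be >= 0", call. = FALSE)
  rows <- purrr::imap(segments, function(seg, i) {
    mask <- stroke_mask(dim(pixels), seg)
    vals <- pixels[mask]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L) {
      return(tibble::tibble(segment = i, mean = NA_real_, area_px2 = 0,
                            integrated_density = NA_real_))
    }
    m <- mean(vals)
    tibble::tibble(segment = i, mean = m, area_px2 = length(vals),
                   integrated_density = max(m - background, 0) * length(vals))
  })
  dplyr::bind_rows(rows)
}

#' Mediatrix line between two nucleus centres
#'
#' Constructs the perpendicular bisector segment between two nucleus
#' centroids, the fallback trace used when no clear junctional signal is
#' visible between a cell pair. The segment is centred on the midpoint and
#' extends `half_length` px to each side; deciding when to use it is left to
#' the analyst, as in manual tracing.
#'
#' @param centre_a,centre_b Length-2 numeric (x, y) nucleus centres, px.
#' @param half_length Half-length of the returned segment, px (default 20).
#' @param width_px Stroke width of the returned [roi_line()].
#' @return An [roi_line()] along the mediatrix.
#' @export
mediatrix_line <- function(centre_a, centre_b, half_length = 20, width_px = 15) {
  mid <- (centre_a + centre_b) / 2
  d <- centre_b - centre_a
  len <- sqrt(sum(d^2))
  if (len == 0) stop("nucleus centres coincide", call. = FALSE)
  perp <- c(-d[2], d[1]) / len
  roi_line(rbind(mid - half_length * perp, mid + half_length * perp), width_px)
}
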