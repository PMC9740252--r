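# Cell-level morphometry: cell segmentation from junctional staining,
# nuclei counting with density classification, focal-adhesion morphometrics
# and per-image feature percentages.

as_ebimage <- function(m) EBImage::Image(m)
eb_matrix <- function(img) {
  m <- EBImage::imageData(img)
  matrix(as.numeric(m), nrow(m), ncol(m))
}

normalise01 <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(NULL)
  (m - rng[1]) / diff(rng)
}

#' Segment cells from a junctional staining image
#'
#' The junctional signal (bright lines over dimmer cytosol) is smoothed,
#' thresholded (Otsu) into a junction mask, small cytosolic objects are
#' cleared and small gaps closed; the connected components of the mask
#' complement are the cell interiors. The interior labels are then grown
#' across the junction band ([EBImage::propagate()], a geodesic Voronoi
#' completion) so that each cell's area covers its full footprint up to the
#' midline of the shared junction. Cells touching the image border are
#' flagged (their areas are censored and excluded from summary statistics by
#' default).
#'
#' @param junction_image An [intensity_image()] of the junctional channel.
#' @param min_cell_area Minimum cell area in µm² (smaller components are
#'   dropped; default 5).
#' @param min_object_px Junction-mask specks smaller than this (px) are
#'   cleared (default 50).
#' @param smooth_sigma Gaussian smoothing sd in px (default 1).
#' @param fill_junctions Grow interior labels across the junction band
#'   (default `TRUE`).
#' @return Object of class `segmentation_map`: `labels` matrix (0 =
#'   unassigned), `per_cell` tibble (`id`, `area_um2`, `centroid_x/y` px,
#'   `border`), `pixel_size`, and a `status` field (`"ok"` or
#'   `"no_junction_signal"`).
#' @export
segment_cells <- function(junction_image, min_cell_area = 5,
                          min_object_px = 50L, smooth_sigma = 1,
                          fill_junctions = TRUE) {
  stopifnot(inherits(junction_image, "intensity_image"))
  ps <- junction_image$pixel_size
  norm <- normalise01(junction_image$pixels)
  empty <- function(status) {
    warning("no junction signal detected; returning empty segmentation",
            call. = FALSE)
    structure(list(labels = matrix(0L, nrow(junction_image$pixels),
                                   ncol(junction_image$pixels)),
                   per_cell = tibble::tibble(id = integer(), area_um2 = numeric(),
                                             centroid_x = numeric(),
                                             centroid_y = numeric(),
                                             border = logical()),
                   pixel_size = ps, status = status),
              class = "segmentation_map")
  }
  if (is.null(norm)) return(empty("no_junction_signal"))
  sm <- eb_matrix(EBImage::gblur(as_ebimage(norm), sigma = smooth_sigma))
  thr <- EBImage::otsu(as_ebimage(sm), range = c(0, 1))
  mask <- sm > thr
  if (!any(mask) || all(mask)) return(empty("no_junction_signal"))
  # clear small cytosolic specks from the junction mask
  lab_mask <- EBImage::bwlabel(as_ebimage(mask))
  sizes <- tabulate(as.integer(lab_mask))
  keep <- which(sizes >= min_object_px)
  mask <- matrix(as.integer(lab_mask) %in% keep, nrow(mask), ncol(mask))
  # close 1-px gaps so cells stay separated
  mask <- eb_matrix(EBImage::closing(as_ebimage(mask * 1),
                                     EBImage::makeBrush(3, "box"))) > 0.5
  interiors <- EBImage::bwlabel(as_ebimage((!mask) * 1))
  labels <- matrix(as.integer(interiors), nrow(mask), ncol(mask))
  sizes <- tabulate(labels)
  keep <- which(sizes * ps^2 >= min_cell_area)
  relab <- integer(max(labels, 1L))
  relab[keep] <- seq_along(keep)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  if (max(labels) == 0L) return(empty("no_junction_signal"))
  if (fill_junctions) {
    grown <- EBImage::propagate(as_ebimage(sm), as_ebimage(labels),
                                lambda = 1e4)
    labels <- matrix(as.integer(grown), nrow(mask), ncol(mask))
  }
  n <- max(labels)
  nr <- nrow(labels); nc <- ncol(labels)
  border_ids <- unique(c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc]))
  px <- rep(seq_len(nc) - 1, each = nr)
  py <- rep(seq_len(nr) - 1, times = nc)
  lv <- as.vector(labels)
  per_cell <- tibble::tibble(
    id = seq_len(n),
    area_um2 = tabulate(labels, nbins = n) * ps^2,
    centroid_x = vapply(seq_len(n), function(i) mean(px[lv == i]), numeric(1)),
    centroid_y = vapply(seq_len(n), function(i) mean(py[lv == i]), numeric(1)),
    border = seq_len(n) %in% border_ids
  )
  structure(list(labels = labels, per_cell = per_cell, pixel_size = ps,
                 status = "ok"),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> %d cells (%d border), status '%s'\n",
              nrow(x$per_cell), sum(x$per_cell$border), x$status))
  invisible(x)
}

#' Count nuclei in a fluorescence image
#'
#' Classical blob segmentation: Gaussian smoothing, Otsu threshold, hole
#' filling, distance-transform watershed to split touching nuclei, then a
#' size floor. A blank image yields zero.
#'
#' @param nuclei_image An [intensity_image()] of a nuclear stain.
#' @param min_area_px Minimum object size in px (default 30).
#' @param smooth_sigma Gaussian smoothing sd in px (default 2).
#' @param watershed_tolerance Minimum distance-map depth between split
#'   objects (default 1).
#' @return Integer count. The labelled matrix is attached as attribute
#'   `labels`.
#' @export
count_nuclei <- function(nuclei_image, min_area_px = 30L, smooth_sigma = 2,
                         watershed_tolerance = 1) {
  stopifnot(inherits(nuclei_image, "intensity_image"))
  norm <- normalise01(nuclei_image$pixels)
  if (is.null(norm)) {
    out <- 0L
    attr(out, "labels") <- matrix(0L, nrow(nuclei_image$pixels),
                                  ncol(nuclei_image$pixels))
    return(out)
  }
  sm <- eb_matrix(EBImage::gblur(as_ebimage(norm), sigma = smooth_sigma))
  thr <- EBImage::otsu(as_ebimage(sm), range = c(0, 1))
  mask <- sm > thr
  mask <- eb_matrix(EBImage::fillHull(as_ebimage(mask * 1))) > 0.5
  dm <- EBImage::distmap(as_ebimage(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  labels <- matrix(as.integer(ws), nrow(mask), ncol(mask))
  sizes <- tabulate(labels)
  ids <- which(sizes >= min_area_px)
  out <- length(ids)
  relab <- integer(max(labels, 1L)); relab[ids] <- seq_along(ids)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  attr(out, "labels") <- labels
  out
}

#' Classify field density from a nuclei count
#'
#' Applies the substrate-specific count thresholds used to discriminate
#' sparse from dense fields in a reference field of 1.6e4 µm² (counts from
#' other field sizes are scaled to the reference area first): on glass,
#' 10–25 nuclei is sparse and more than 40 dense; on 40 kPa hydrogels, 15–30
#' is sparse and more than 50 dense; everything else is intermediate. Fields
#' on 1 kPa hydrogels are not classified (cells form densely packed islands
#' in all conditions there).
#'
#' @param count Nuclei count (>= 0).
#' @param substrate One of `"glass"`, `"kPa40"`, `"kPa1"`.
#' @param field_area_um2 Area of the imaged field in µm² (default the
#'   reference 1.6e4).
#' @return One-row tibble: `count`, `substrate`, `scaled_count`, `call`
#'   (factor sparse/intermediate/dense/not_classified). The area-scaling
#'   assumption is recorded in the `scaled` column.
#' @export
classify_density <- function(count, substrate = c("glass", "kPa40", "kPa1"),
                             field_area_um2 = 1.6e4) {
  if (!is.numeric(count) || count < 0) stop("`count` must be >= 0", call. = FALSE)
  substrate <- tryCatch(match.arg(substrate),
                        error = function(e) stop("unknown substrate",
                                                 call. = FALSE))
  scaled <- count * 1.6e4 / field_area_um2
  call <- if (substrate == "kPa1") {
    "not_classified"
  } else if (substrate == "glass") {
    if (scaled >= 10 && scaled <= 25) "sparse"
    else if (scaled > 40) "dense"
    else "intermediate"
  } else {
    if (scaled >= 15 && scaled <= 30) "sparse"
    else if (scaled > 50) "dense"
    else "intermediate"
  }
  tibble::tibble(count = count, substrate = substrate, scaled_count = scaled,
                 scaled = field_area_um2 != 1.6e4,
                 call = factor(call, levels = c("sparse", "intermediate",
                                                "dense", "not_classified")))
}

#' Maximum Feret (caliper) diameter of a point set
#'
#' Exact maximum caliper width: the largest pairwise distance between convex
#' hull vertices, which equals the maximum over all orientations of the
#' projected extent.
#'
#' @param points An n x 2 matrix of (x, y) coordinates.
#' @return The maximum Feret diameter in the units of `points`.
#' @export
feret_diameter <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) return(0)
  hull <- points[grDevices::chull(points), , drop = FALSE]
  if (nrow(hull) < 2L) return(0)
  d2max <- 0
  for (i in seq_len(nrow(hull) - 1L)) {
    dx <- hull[(i + 1L):nrow(hull), 1] - hull[i, 1]
    dy <- hull[(i + 1L):nrow(hull), 2] - hull[i, 2]
    d2max <- max(d2max, dx * dx + dy * dy)
  }
  sqrt(d2max)
}

# Pixel-centre coordinates of one labelled object.
object_points <- function(labels, id) {
  idx <- which(labels == id, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

#' Focal-adhesion morphometrics
#'
#' Segments focal adhesions from a basal-plane image (e.g. vinculin
#' staining): morphological (rolling-ball-style) background subtraction,
#' locally adaptive thresholding, distance-transform watershed splitting of
#' fused objects, then per-object area and maximum Feret diameter and their
#' per-image means.
#'
#' @param image An [intensity_image()] of the basal plane.
#' @param min_area Minimum object area in µm² (default 0.1).
#' @param background_radius Radius of the background (opening) structuring
#'   disc, px (default 15).
#' @param adaptive_halfwidth Half-width of the adaptive-threshold window, px
#'   (window side = 2 x halfwidth + 1; default 25).
#' @param adaptive_offset Offset added to the local mean inside the adaptive
#'   threshold (normalised intensity scale; default 0.01, just above
#'   numerical round-off so a uniform zero background stays off).
#' @param watershed_tolerance Watershed splitting tolerance (default 1).
#' @return Object of class `adhesion_set`: `objects` tibble (`id`,
#'   `area_um2`, `max_feret_um`), `per_image` one-row tibble of means and
#'   the object count, and the label matrix.
#' @export
adhesion_morphometrics <- function(image, min_area = 0.1,
                                   background_radius = 15L,
                                   adaptive_halfwidth = 25L,
                                   adaptive_offset = 0.01,
                                   watershed_tolerance = 1) {
  stopifnot(inherits(image, "intensity_image"))
  ps <- image$pixel_size
  empty <- function() {
    structure(list(
      objects = tibble::tibble(id = integer(), area_um2 = numeric(),
                               max_feret_um = numeric()),
      per_image = tibble::tibble(n_objects = 0L, mean_area_um2 = NA_real_,
                                 mean_max_feret_um = NA_real_),
      labels = matrix(0L, nrow(image$pixels), ncol(image$pixels)),
      pixel_size = ps), class = "adhesion_set")
  }
  norm <- normalise01(image$pixels)
  if (is.null(norm)) return(empty())
  brush_sz <- 2L * as.integer(background_radius) + 1L
  bg <- eb_matrix(EBImage::opening(as_ebimage(norm),
                                   EBImage::makeBrush(brush_sz, "disc")))
  fg <- pmax(norm - bg, 0)
  bin <- eb_matrix(EBImage::thresh(as_ebimage(fg), w = adaptive_halfwidth,
                                   h = adaptive_halfwidth,
                                   offset = adaptive_offset)) > 0.5
  if (!any(bin)) return(empty())
  dm <- EBImage::distmap(as_ebimage(bin * 1))
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  labels <- matrix(as.integer(ws), nrow(bin), ncol(bin))
  sizes <- tabulate(labels)
  ids <- which(sizes * ps^2 >= min_area)
  if (length(ids) == 0L) return(empty())
  relab <- integer(max(labels)); relab[ids] <- seq_along(ids)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  objects <- purrr::map_dfr(seq_along(ids), function(i) {
    tibble::tibble(
      id = i,
      area_um2 = sizes[ids[i]] * ps^2,
      max_feret_um = feret_diameter(object_points(labels, i)) * ps
    )
  })
  per_image <- tibble::tibble(
    n_objects = nrow(objects),
    mean_area_um2 = mean(objects$area_um2),
    mean_max_feret_um = mean(objects$max_feret_um)
  )
  structure(list(objects = objects, per_image = per_image, labels = labels,
                 pixel_size = ps),
            class = "adhesion_set")
}

#' @export
print.adhesion_set <- function(x, ...) {
  cat(sprintf("<adhesion_set> %d objects, mean area %.3g um^2, mean Feret %.3g um\n",
              x$per_image$n_objects, x$per_image$mean_area_um2,
              x$per_image$mean_max_feret_um))
  invisible(x)
}

#' Percentage of cells displaying a feature
#'
#' @param n_positive Number of cells displaying the feature.
#' @param n_cells Total cells in the image (> 0).
#' @return Percentage, `100 * n_positive / n_cells`.
#' @export
feature_percentage <- function(n_positive, n_cells) {
  if (any(n_cells <= 0)) stop("`n_cells` must be > 0", call. = FALSE)
  if (any(n_positive < 0 | n_positive > n_cells)) {
    stop("`n_positive` must lie in [0, n_cells]", call. = FALSE)
  }
  100 * n_positive / n_cells
}
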