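# Calibrated image containers, focus handling and ROI geometry shared by all
# quantification pipelines.
#
# Coordinate convention (used everywhere in the package): origin at the centre
# of the top-left pixel, x rightward, y downward, 0-based. A pixel (i, j) of
# the intensity matrix (row i = y, column j = x, both 1-based in R) therefore
# has its centre at (x, y) = (j - 1, i - 1).

#' Calibrated intensity image
#'
#' Bundles a 2D matrix of non-negative intensities with its pixel size in
#' micrometres per pixel and a free-text channel label. This is the carrier
#' for every stained channel handled by the package.
#'
#' @param pixels Numeric matrix of non-negative intensities (rows = y,
#'   columns = x).
#' @param pixel_size Pixel size in µm/px, strictly positive.
#' @param channel Free-text channel label.
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(pixels, pixel_size = 1, channel = "") {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) < 1L) {
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (any(pixels < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         channel = as.character(channel)),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, %.4g um/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$channel))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

#' Ordered stack of co-registered images
#'
#' @param slices List of [intensity_image()] objects sharing shape and pixel
#'   size.
#' @param z_step Axial spacing between slices in µm (required > 0 when the
#'   stack has more than one slice).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(slices, z_step = 1) {
  if (!is.list(slices) || length(slices) < 1L) {
    stop("`slices` must be a non-empty list of intensity images", call. = FALSE)
  }
  slices <- lapply(slices, function(s) {
    if (inherits(s, "intensity_image")) s else intensity_image(s)
  })
  d <- dim(slices[[1]]$pixels)
  ok <- vapply(slices, function(s) identical(dim(s$pixels), d), logical(1))
  if (!all(ok)) stop("all slices must share the same shape", call. = FALSE)
  if (length(slices) > 1L && (!is.numeric(z_step) || z_step <= 0)) {
    stop("`z_step` must be positive for multi-slice stacks", call. = FALSE)
  }
  structure(list(slices = slices, z_step = as.numeric(z_step)),
            class = "image_stack")
}

#' @export
length.image_stack <- function(x) length(x$slices)

#' Polyline region of interest with a stroke width
#'
#' Mirrors the manual line tool used to trace junctions: an ordered polyline
#' in pixel coordinates, stroked to `width_px`. A pixel belongs to the stroke
#' when its centre lies within `width_px / 2` (Euclidean) of the polyline.
#'
#' @param vertices Two-column matrix (x, y) of at least two vertices, pixel
#'   coordinates.
#' @param width_px Stroke width in pixels (>= 1).
#' @return An object of class `roi_line`.
#' @export
roi_line <- function(vertices, width_px = 1) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L) {
    stop("`vertices` must be an n x 2 matrix with n >= 2", call. = FALSE)
  }
  if (width_px < 1) stop("`width_px` must be >= 1", call. = FALSE)
  structure(list(vertices = unname(vertices), width_px = as.numeric(width_px)),
            class = "roi_line")
}

#' Polygonal region of interest
#'
#' @param polygon Two-column matrix (x, y) of at least three vertices forming
#'   a simple closed polygon (closure is implicit).
#' @return An object of class `roi_region`.
#' @export
roi_region <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    stop("`polygon` must be an n x 2 matrix with n >= 3", call. = FALSE)
  }
  structure(list(polygon = unname(polygon)), class = "roi_region")
}

# ---- focus handling ---------------------------------------------------------

# 3x3 Laplacian high-pass response; the focus score of a slice is the variance
# of this response, which is monotone decreasing under Gaussian defocus.
laplacian_response <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  up + dn + lf + rt - 4 * m
}

focus_score <- function(m) stats::var(as.vector(laplacian_response(m)))

#' Select the most in-focus slice of a stack
#'
#' Scores each slice by the variance of a 3x3 Laplacian high-pass response
#' and returns the 1-based index of the slice with the highest score. Ties
#' are broken towards the lowest index.
#'
#' @param stack An [image_stack()].
#' @return Integer slice index (1-based).
#' @export
find_focused_slice <- function(stack) {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  scores <- vapply(stack$slices, function(s) focus_score(s$pixels), numeric(1))
  which.max(scores)
}

# Running box mean with edge replication, window w (odd).
box_mean <- function(m, w) {
  half <- (w - 1L) %/% 2L
  pad_idx <- function(n) c(rep(1L, half), seq_len(n), rep(n, half))
  p <- m[pad_idx(nrow(m)), pad_idx(ncol(m)), drop = FALSE]
  cs <- apply(p, 2, cumsum)
  cs <- rbind(0, cs)
  rows <- cs[seq_len(nrow(m)) + w, , drop = FALSE] - cs[seq_len(nrow(m)), , drop = FALSE]
  cs2 <- t(apply(rows, 1, cumsum))
  cs2 <- cbind(0, cs2)
  out <- cs2[, seq_len(ncol(m)) + w, drop = FALSE] - cs2[, seq_len(ncol(m)), drop = FALSE]
  out / (w * w)
}

#' Extended depth-of-focus projection
#'
#' Projects a stack to a single image by selecting, per pixel, the value from
#' the locally sharpest slice. Local sharpness is the mean squared Laplacian
#' response in a square window around the pixel.
#'
#' @param stack An [image_stack()].
#' @param window Side of the square focus window in pixels (odd, default 9).
#' @return An [intensity_image()] with the shape of the slices.
#' @export
extended_focus_projection <- function(stack, window = 9L) {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  n <- length(stack$slices)
  first <- stack$slices[[1]]
  if (n == 1L) return(first)
  best_score <- matrix(-Inf, nrow(first$pixels), ncol(first$pixels))
  out <- first$pixels
  for (s in stack$slices) {
    sc <- box_mean(laplacian_response(s$pixels)^2, window)
    take <- sc > best_score
    out[take] <- s$pixels[take]
    best_score[take] <- sc[take]
  }
  intensity_image(out, first$pixel_size, first$channel)
}

# ---- ROI geometry -----------------------------------------------------------

# Minimum distance from points (x, y) to a polyline given as an n x 2 matrix.
dist_to_polyline <- function(x, y, vertices) {
  d2 <- rep(Inf, length(x))
  for (i in seq_len(nrow(vertices) - 1L)) {
    ax <- vertices[i, 1]; ay <- vertices[i, 2]
    bx <- vertices[i + 1L, 1]; by <- vertices[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    if (len2 == 0) {
      dx <- x - ax; dy <- y - ay
    } else {
      t <- pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2))
      dx <- x - (ax + t * vx); dy <- y - (ay + t * vy)
    }
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# Logical mask of pixels whose centres fall inside the stroked polyline.
stroke_mask <- function(img_dim, roi) {
  stopifnot(inherits(roi, "roi_line"))
  nr <- img_dim[1]; nc <- img_dim[2]
  half <- roi$width_px / 2
  xmin <- max(1L, floor(min(roi$vertices[, 1]) - half) + 1L)
  xmax <- min(nc, ceiling(max(roi$vertices[, 1]) + half) + 1L)
  ymin <- max(1L, floor(min(roi$vertices[, 2]) - half) + 1L)
  ymax <- min(nr, ceiling(max(roi$vertices[, 2]) + half) + 1L)
  mask <- matrix(FALSE, nr, nc)
  if (xmin > xmax || ymin > ymax) return(mask)
  cols <- xmin:xmax; rows <- ymin:ymax
  gx <- rep(cols - 1L, each = length(rows))
  gy <- rep(rows - 1L, times = length(cols))
  d <- dist_to_polyline(gx, gy, roi$vertices)
  mask[cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))] <-
    d <= half
  mask
}

# Even-odd point-in-polygon test for pixel centres.
polygon_mask <- function(img_dim, roi) {
  stopifnot(inherits(roi, "roi_region"))
  poly <- roi$polygon
  nr <- img_dim[1]; nc <- img_dim[2]
  xmin <- max(1L, floor(min(poly[, 1])) + 1L)
  xmax <- min(nc, ceiling(max(poly[, 1])) + 1L)
  ymin <- max(1L, floor(min(poly[, 2])) + 1L)
  ymax <- min(nr, ceiling(max(poly[, 2])) + 1L)
  mask <- matrix(FALSE, nr, nc)
  if (xmin > xmax || ymin > ymax) return(mask)
  cols <- xmin:xmax; rows <- ymin:ymax
  gx <- rep(cols - 1L, each = length(rows))
  gy <- rep(rows - 1L, times = length(cols))
  inside <- rep(FALSE, length(gx))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > gy) != (yj > gy)) &
      (gx < (xj - xi) * (gy - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mask[cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))] <-
    inside
  mask
}

#' Mean intensity along a stroked line ROI
#'
#' Dilates the polyline to its stroke width and averages the pixel values
#' whose centres fall inside the stroke.
#'
#' @param image An [intensity_image()].
#' @param roi An [roi_line()].
#' @return Mean intensity (scalar).
#' @export
mean_intensity_along <- function(image, roi) {
  stopifnot(inherits(image, "intensity_image"))
  mask <- stroke_mask(dim(image$pixels), roi)
  if (!any(mask)) stop("ROI lies entirely outside the image", call. = FALSE)
  mean(image$pixels[mask])
}

# ---- file formats -----------------------------------------------------------

#' Read a grayscale TIFF as an intensity image or stack
#'
#' Plain single- or multi-page grayscale TIFF with 8-, 16- or 32-bit
#' unsigned integer samples. Values are returned on their native integer
#' scale. The pixel size is not stored in plain TIFF, so it is supplied by
#' the caller (e.g. from a sidecar configuration).
#'
#' @param path Path to the TIFF file.
#' @param pixel_size Pixel size in µm/px.
#' @param channel Channel label attached to the result.
#' @param z_step Axial step for multi-page files.
#' @return An [intensity_image()] (single page) or [image_stack()].
#' @export
read_image_tiff <- function(path, pixel_size = 1, channel = "", z_step = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) any(p < 0), logical(1)))) {
    # 32-bit unsigned samples overflow R's signed integers; re-read on the
    # normalised scale and restore the native range
    pages <- lapply(tiff::readTIFF(path, all = TRUE), function(p) {
      round(p * (2^32 - 1))
    })
  }
  imgs <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    intensity_image(p, pixel_size, channel)
  })
  if (length(imgs) == 1L) imgs[[1]] else image_stack(imgs, z_step)
}

#' Write an intensity image (or stack) to a grayscale TIFF
#'
#' Intensities are rounded to unsigned integers at the requested bit depth
#' (they must fit: values above `2^bits - 1` are an error, rescale first).
#' Integer-valued images round-trip exactly through
#' [read_image_tiff()]; for continuous-valued maps (e.g. FRET efficiency)
#' the tabular exports are the quantitative record and TIFF export is for
#' viewing.
#'
#' @param image An [intensity_image()] or [image_stack()].
#' @param path Output path.
#' @param bits Bits per sample: 8, 16 (default) or 32.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L, 32L))
  mats <- if (inherits(image, "image_stack")) {
    lapply(image$slices, function(s) s$pixels)
  } else {
    list(image$pixels)
  }
  maxv <- 2^bits - 1
  if (any(vapply(mats, function(m) any(m > maxv), logical(1)))) {
    stop("intensities exceed the ", bits, "-bit range; rescale first",
         call. = FALSE)
  }
  tiff::writeTIFF(lapply(mats, function(m) round(m) / maxv), path,
                  bits.per.sample = as.integer(bits), reduce = FALSE)
  invisible(path)
}

#' Read ROI annotations from JSON
#'
#' The annotation format is a JSON array of objects
#' `{"type": "line"|"region", "vertices": [[x, y], ...], "width_px": int}`
#' (`width_px` only for lines).
#'
#' @param path Path to the JSON file.
#' @return A list of [roi_line()] / [roi_region()] objects.
#' @export
read_roi_json <- function(path) {
  ann <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(ann, function(a) {
    v <- do.call(rbind, lapply(a$vertices, unlist))
    switch(a$type,
      line = roi_line(v, width_px = a$width_px %||% 1),
      region = roi_region(v),
      stop("unknown ROI type: ", a$type, call. = FALSE)
    )
  })
}

#' Write ROI annotations to JSON
#'
#' @param rois List of [roi_line()] / [roi_region()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(rois, path) {
  ann <- lapply(rois, function(r) {
    if (inherits(r, "roi_line")) {
      list(type = "line", vertices = apply(r$vertices, 1, as.list),
           width_px = r$width_px)
    } else {
      list(type = "region", vertices = apply(r$polygon, 1, as.list))
    }
  })
  jsonlite::write_json(ann, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
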