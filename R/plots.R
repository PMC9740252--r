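# ggplot2 visualisations of the package's result objects.

#' @describeIn intensity_image Raster plot of the image, y axis flipped so
#'   the display matches the pixel coordinate convention (origin top-left).
#' @param object An `intensity_image`.
#' @param ... Unused.
#' @export
autoplot.intensity_image <- function(object, ...) {
  nr <- nrow(object$pixels); nc <- ncol(object$pixels)
  df <- tibble::tibble(
    x = rep(seq_len(nc) - 1, each = nr),
    y = rep(seq_len(nr) - 1, times = nc),
    intensity = as.vector(object$pixels)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$channel, x = "x (px)", y = "y (px)")
}

field_autoplot <- function(df, comp_x, comp_y, unit, title) {
  sub <- df[seq(1, nrow(df), by = max(1L, nrow(df) %/% 400L)), ]
  scale <- 0.4 * min(diff(sort(unique(df$x)))[1], diff(sort(unique(df$y)))[1]) /
    max(df$magnitude, 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$magnitude)) +
    ggplot2::geom_segment(
      data = sub,
      ggplot2::aes(xend = .data$x + scale * .data[[comp_x]],
                   yend = .data$y + scale * .data[[comp_y]]),
      linewidth = 0.3, colour = "white",
      arrow = ggplot2::arrow(length = ggplot2::unit(1, "mm"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = unit) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "x (µm)", y = "y (µm)")
}

#' @describeIn displacement_field Magnitude raster with displacement arrows.
#' @param object A `displacement_field`.
#' @export
autoplot.displacement_field <- function(object, ...) {
  field_autoplot(tidy.displacement_field(object), "ux", "uy",
                 "|u| (µm)", "displacement field")
}

#' @describeIn traction_field Stress-map raster with traction arrows.
#' @param object A `traction_field`.
#' @export
autoplot.traction_field <- function(object, ...) {
  field_autoplot(tidy.traction_field(object), "tx", "ty",
                 "|T| (Pa)", "traction field")
}

#' @describeIn fret_efficiency_map Efficiency raster (NA pixels blank).
#' @param object An `efficiency_map`.
#' @export
autoplot.efficiency_map <- function(object, ...) {
  df <- tidy.efficiency_map(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$efficiency)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "apparent FRET efficiency",
                  x = "x (µm)", y = "y (µm)")
}

#' @describeIn segment_cells Random-colour label rendering of the
#'   segmentation.
#' @param object A `segmentation_map`.
#' @export
autoplot.segmentation_map <- function(object, ...) {
  nr <- nrow(object$labels); nc <- ncol(object$labels)
  df <- tibble::tibble(
    x = rep(seq_len(nc) - 1, each = nr),
    y = rep(seq_len(nr) - 1, times = nc),
    cell = factor(as.vector(object$labels))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$cell)) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "cell segmentation", x = "x (px)", y = "y (px)")
}

#' @describeIn segment_islands Binary island mask.
#' @param object An `island_set`.
#' @export
autoplot.island_set <- function(object, ...) {
  nr <- nrow(object$mask); nc <- ncol(object$mask)
  df <- tibble::tibble(
    x = rep(seq_len(nc) - 1, each = nr),
    y = rep(seq_len(nr) - 1, times = nc),
    island = as.vector(object$mask)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$island)) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "black", `TRUE` = "white")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "island mask", x = "x (px)", y = "y (px)")
}

#' @describeIn strand_network Strand polylines with the apical strand
#'   highlighted.
#' @param object A `strand_network`.
#' @export
autoplot.strand_network <- function(object, ...) {
  df <- purrr::map_dfr(object$strands, function(st) {
    purrr::imap_dfr(st$segments, function(seg, k) {
      tibble::tibble(id = st$id, part = paste(st$id, k),
                     x = seg[, 1], y = seg[, 2],
                     apical = identical(st$id, object$apical_id))
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$part,
                                   colour = .data$apical)) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "strand network", x = "x (nm)", y = "y (nm)")
}
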