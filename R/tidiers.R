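# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

field_tibble <- function(a, b, h, names) {
  nr <- nrow(a); nc <- ncol(a)
  out <- tibble::tibble(
    x = rep((seq_len(nc) - 1) * h, each = nr),
    y = rep((seq_len(nr) - 1) * h, times = nc),
    a = as.vector(a), b = as.vector(b)
  )
  names(out)[3:4] <- names
  out
}

#' @describeIn displacement_field Tidy to a tibble with node coordinates
#'   (µm), components `ux`, `uy` and `magnitude`.
#' @param x A `displacement_field`.
#' @param ... Unused.
#' @export
tidy.displacement_field <- function(x, ...) {
  dplyr::mutate(field_tibble(x$ux, x$uy, x$h, c("ux", "uy")),
                magnitude = sqrt(.data$ux^2 + .data$uy^2))
}

#' @describeIn traction_field Tidy to a tibble with node coordinates (µm),
#'   components `tx`, `ty` and `magnitude` (Pa).
#' @param x A `traction_field`.
#' @param ... Unused.
#' @export
tidy.traction_field <- function(x, ...) {
  dplyr::mutate(field_tibble(x$tx, x$ty, x$h, c("tx", "ty")),
                magnitude = sqrt(.data$tx^2 + .data$ty^2))
}

#' @describeIn fret_efficiency_map Tidy to a tibble of pixel coordinates
#'   (µm) and efficiency values.
#' @param x An `efficiency_map`.
#' @param ... Unused.
#' @export
tidy.efficiency_map <- function(x, ...) {
  nr <- nrow(x$pixels); nc <- ncol(x$pixels)
  tibble::tibble(
    x = rep((seq_len(nc) - 1) * x$pixel_size, each = nr),
    y = rep((seq_len(nr) - 1) * x$pixel_size, times = nc),
    efficiency = as.vector(x$pixels)
  )
}

#' @describeIn fret_efficiency_map One-row summary of an efficiency map:
#'   defined fraction, mean/median efficiency and the calibration used.
#' @export
glance.efficiency_map <- function(x, ...) {
  v <- x$pixels[is.finite(x$pixels)]
  tibble::tibble(
    n_defined = length(v),
    fraction_defined = length(v) / length(x$pixels),
    mean_efficiency = if (length(v)) mean(v) else NA_real_,
    median_efficiency = if (length(v)) stats::median(v) else NA_real_,
    beta = x$beta, gamma = x$gamma
  )
}

#' @describeIn segment_cells Per-cell table (`id`, `area_um2`, centroid,
#'   `border`).
#' @param x A `segmentation_map`.
#' @param ... Unused.
#' @export
tidy.segmentation_map <- function(x, ...) x$per_cell

#' @describeIn segment_cells One-row summary; area statistics exclude
#'   border-touching (censored) cells.
#' @export
glance.segmentation_map <- function(x, ...) {
  interior <- dplyr::filter(x$per_cell, !.data$border)
  tibble::tibble(
    n_cells = nrow(x$per_cell),
    n_border = sum(x$per_cell$border),
    mean_area_um2 = if (nrow(interior)) mean(interior$area_um2) else NA_real_,
    median_area_um2 = if (nrow(interior)) stats::median(interior$area_um2)
      else NA_real_,
    status = x$status
  )
}

#' @describeIn adhesion_morphometrics Per-object table.
#' @param x An `adhesion_set`.
#' @param ... Unused.
#' @export
tidy.adhesion_set <- function(x, ...) x$objects

#' @describeIn adhesion_morphometrics Per-image means (the reporting unit).
#' @export
glance.adhesion_set <- function(x, ...) x$per_image

#' @describeIn segment_islands Per-island table.
#' @param x An `island_set`.
#' @param ... Unused.
#' @export
tidy.island_set <- function(x, ...) x$islands

#' @describeIn segment_islands One-row summary: coverage, count and
#'   morphogenesis index.
#' @export
glance.island_set <- function(x, ...) morphogenesis_metrics(x)

#' @describeIn strand_network Per-strand table: id, appearance, number of
#'   segments, total traced length (nm).
#' @param x A `strand_network`.
#' @param ... Unused.
#' @export
tidy.strand_network <- function(x, ...) {
  purrr::map_dfr(x$strands, function(st) {
    len <- sum(vapply(st$segments, function(seg) {
      sum(sqrt(rowSums(diff(seg)^2)))
    }, numeric(1)))
    tibble::tibble(id = st$id,
                   appearance = st$appearance %||% NA_character_,
                   n_segments = length(st$segments),
                   length_nm = len,
                   apical = identical(st$id, x$apical_id))
  })
}

#' @describeIn strand_counts Per-grid-line counts.
#' @param x A `strand_counts` object.
#' @param ... Unused.
#' @export
tidy.strand_counts <- function(x, ...) x$per_line

#' @describeIn strand_counts One-row summary with the mean strand number.
#' @export
glance.strand_counts <- function(x, ...) {
  tibble::tibble(n_lines = nrow(x$per_line),
                 mean_strand_number = x$mean_strand_number)
}
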