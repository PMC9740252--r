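# Ground-truthed synthetic tight-junction strand meshworks: roughly
# horizontal polylines stacked over the meshwork depth with sinusoidal
# jitter, optional gaps cut into strands, and per-strand appearance labels.

#' Generate a synthetic strand meshwork with ground truth
#'
#' Strand `i` runs horizontally at vertical offset `depth_nm * (i - 1) /
#' (n_strands - 1)` (the first strand, at the top, is apical), with
#' sinusoidal vertical jitter of amplitude `jitter_amp_nm` and a random
#' phase per strand. Requested gaps are cut into the named strands at random
#' horizontal positions, splitting the polyline into consecutive segments
#' whose end-to-end distance equals the requested gap (up to the jitter
#' slope).
#'
#' @param n_strands Number of strands (>= 1).
#' @param depth_nm Meshwork depth (apical to contra-apical), nm.
#' @param breaks Tibble/data frame with columns `strand` (id) and `gap_nm`
#'   (> 0), or `NULL` for none.
#' @param length_nm Horizontal extent of the meshwork (default 2400).
#' @param jitter_amp_nm Sinusoidal jitter amplitude (default 5).
#' @param jitter_wavelength_nm Jitter wavelength (default 600).
#' @param vertex_step_nm Vertex spacing along each strand (default 25).
#' @param appearance Per-strand appearance labels (recycled; default
#'   `"particle"`).
#' @param seed RNG seed.
#' @return List with `network` ([strand_network()]) and `truth` (list:
#'   `n_strands`, `depth_nm`, `breaks`, `appearance`).
#' @export
make_strand_network <- function(n_strands, depth_nm = 300, breaks = NULL,
                                length_nm = 2400, jitter_amp_nm = 5,
                                jitter_wavelength_nm = 600,
                                vertex_step_nm = 25,
                                appearance = "particle", seed = 1L) {
  if (n_strands < 1) stop("`n_strands` must be >= 1", call. = FALSE)
  if (depth_nm < 0) stop("`depth_nm` must be >= 0", call. = FALSE)
  if (!is.null(breaks) && nrow(breaks) > 0 && any(breaks$gap_nm <= 0)) {
    stop("gap lengths must be > 0", call. = FALSE)
  }
  local_seed(seed, {
    app <- rep_len(appearance, n_strands)
    offsets <- if (n_strands == 1L) 0 else
      depth_nm * (seq_len(n_strands) - 1) / (n_strands - 1)
    xs <- seq(0, length_nm, by = vertex_step_nm)
    strands <- vector("list", n_strands)
    truth_breaks <- tibble::tibble(strand = integer(), gap_nm = numeric())
    for (i in seq_len(n_strands)) {
      phase <- stats::runif(1, 0, 2 * pi)
      yfun <- function(x) offsets[i] +
        jitter_amp_nm * sin(2 * pi * x / jitter_wavelength_nm + phase)
      poly <- cbind(xs, yfun(xs))
      segs <- list(poly)
      gaps <- if (!is.null(breaks) && nrow(breaks) > 0) {
        breaks$gap_nm[breaks$strand == i]
      } else numeric(0)
      if (length(gaps) > 0) {
        # spread the cuts over the middle of the strand, well separated
        xc <- length_nm * seq(0.25, 0.75, length.out = length(gaps) + 2L)
        xc <- xc[-c(1L, length(xc))]
        for (g in seq_along(gaps)) {
          lo <- xc[g] - gaps[g] / 2; hi <- xc[g] + gaps[g] / 2
          new_segs <- list()
          for (seg in segs) {
            if (min(seg[, 1]) < lo && max(seg[, 1]) > hi) {
              left <- seg[seg[, 1] < lo, , drop = FALSE]
              right <- seg[seg[, 1] > hi, , drop = FALSE]
              left <- rbind(left, c(lo, yfun(lo)))
              right <- rbind(c(hi, yfun(hi)), right)
              new_segs <- c(new_segs, list(left, right))
              truth_breaks <- dplyr::bind_rows(
                truth_breaks, tibble::tibble(strand = i, gap_nm = gaps[g]))
            } else {
              new_segs <- c(new_segs, list(seg))
            }
          }
          segs <- new_segs
        }
      }
      strands[[i]] <- list(id = i, appearance = app[i],
                           segments = lapply(segs, unname))
    }
    net <- strand_network(strands, apical_id = 1)
    list(network = net,
         truth = list(n_strands = n_strands,
                      depth_nm = if (n_strands == 1L) 0 else depth_nm,
                      breaks = truth_breaks, appearance = app))
  })
}
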