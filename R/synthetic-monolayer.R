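# Ground-truthed synthetic epithelial monolayers: a Voronoi-like cell mosaic
# with bright junctional bands over dimmer cytosol, plus a nuclei channel.
# These fixtures emulate stained MDCK monolayers at high magnification and
# carry the full generative truth so downstream measurements can be validated
# by parameter recovery.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic epithelial monolayer with ground truth
#'
#' Builds a Voronoi-like mosaic of `n_cells` cells from jittered-grid seed
#' points, draws the junction channel as a bright band (level `J`) of
#' half-width `junction_halfwidth` pixels around the 1-px inter-cell skeleton
#' over cytosol at level `C`, and a nuclei channel with one Gaussian blob per
#' cell over background `B`. Additive Gaussian noise of standard deviation
#' `noise_sd` is applied to both channels. The returned truth records the
#' label map, junction skeleton and band, per-cell areas, seed (nucleus)
#' positions and the cell-adjacency edge pixels.
#'
#' @param n_cells Number of cells (>= 1).
#' @param size Image side in pixels (square image).
#' @param pixel_size Pixel size, µm/px.
#' @param J,C,B Junction, cytosol and background intensity levels; must
#'   satisfy J > C > B >= 0.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param junction_halfwidth Half-width of the rendered junction band, px.
#' @param nucleus_sigma Gaussian sd of the nucleus blob, px.
#' @param seed RNG seed; generators are pure functions of (parameters, seed).
#' @return A list with elements `junction` and `nuclei` (both
#'   [intensity_image()]) and `truth` (list: `label_map`, `junction_mask`,
#'   `band_mask`, `per_cell` tibble with areas in µm², `edges` tibble,
#'   `intensities`, `seed_points`).
#' @export
make_monolayer <- function(n_cells, size = 512L, pixel_size = 0.1,
                           J = 200, C = 100, B = 0, noise_sd = 0,
                           junction_halfwidth = 8, nucleus_sigma = 6,
                           seed = 1L) {
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  if (size < 4 || pixel_size <= 0) stop("non-positive sizes", call. = FALSE)
  if (!(J > C && C > B && B >= 0)) stop("need J > C > B >= 0", call. = FALSE)
  local_seed(seed, {
    nr <- nc <- as.integer(size)
    # jittered-grid seed points give a regular-ish mosaic without tiny cells
    g <- ceiling(sqrt(n_cells))
    cellw <- size / g
    grid_xy <- expand.grid(ix = seq_len(g) - 1, iy = seq_len(g) - 1)
    grid_xy <- grid_xy[sample.int(nrow(grid_xy)), , drop = FALSE]
    grid_xy <- grid_xy[seq_len(n_cells), , drop = FALSE]
    sx <- (grid_xy$ix + 0.5) * cellw + stats::runif(n_cells, -0.25, 0.25) * cellw
    sy <- (grid_xy$iy + 0.5) * cellw + stats::runif(n_cells, -0.25, 0.25) * cellw
    seeds <- cbind(x = sx, y = sy)

    px <- rep(seq_len(nc) - 1, each = nr)   # x per matrix element
    py <- rep(seq_len(nr) - 1, times = nc)  # y per matrix element
    best <- rep(Inf, nr * nc)
    lab <- rep(1L, nr * nc)
    for (i in seq_len(n_cells)) {
      d2 <- (px - seeds[i, 1])^2 + (py - seeds[i, 2])^2
      take <- d2 < best
      lab[take] <- i
      best[take] <- d2[take]
    }
    label_map <- matrix(lab, nr, nc)

    # 1-px skeleton where the label changes (right/down neighbour), plus the
    # image border ring (outline of the mosaic)
    skel <- matrix(FALSE, nr, nc)
    edges <- list()
    if (n_cells > 1L) {
      dh <- label_map[, -nc, drop = FALSE] != label_map[, -1L, drop = FALSE]
      dv <- label_map[-nr, , drop = FALSE] != label_map[-1L, , drop = FALSE]
      skel[, -nc][dh] <- TRUE
      skel[-nr, ][dv] <- TRUE
      idx_h <- which(dh, arr.ind = TRUE)
      idx_v <- which(dv, arr.ind = TRUE)
      # edge pixels are recorded at the marked skeleton pixel centres so that
      # lines fitted through them sit on the skeleton itself
      pair_tbl <- rbind(
        if (nrow(idx_h)) cbind(
          a = label_map[idx_h], b = label_map[cbind(idx_h[, 1], idx_h[, 2] + 1L)],
          x = idx_h[, 2] - 1, y = idx_h[, 1] - 1),
        if (nrow(idx_v)) cbind(
          a = label_map[idx_v], b = label_map[cbind(idx_v[, 1] + 1L, idx_v[, 2])],
          x = idx_v[, 2] - 1, y = idx_v[, 1] - 1)
      )
      ab <- cbind(pmin(pair_tbl[, "a"], pair_tbl[, "b"]),
                  pmax(pair_tbl[, "a"], pair_tbl[, "b"]))
      edges <- tibble::tibble(cell_a = ab[, 1], cell_b = ab[, 2],
                              x = pair_tbl[, "x"], y = pair_tbl[, "y"])
    } else {
      edges <- tibble::tibble(cell_a = integer(), cell_b = integer(),
                              x = numeric(), y = numeric())
    }
    skel[1, ] <- TRUE; skel[nr, ] <- TRUE; skel[, 1] <- TRUE; skel[, nc] <- TRUE

    dist_to_skel <- as.matrix(EBImage::distmap(EBImage::Image(1 - skel)))
    band <- dist_to_skel <= junction_halfwidth

    junction <- matrix(C, nr, nc)
    junction[band] <- J
    nuclei <- matrix(B, nr, nc)
    for (i in seq_len(n_cells)) {
      blob <- exp(-((px - seeds[i, 1])^2 + (py - seeds[i, 2])^2) /
                    (2 * nucleus_sigma^2))
      nuclei <- nuclei + matrix((J - B) * blob, nr, nc)
    }
    if (noise_sd > 0) {
      junction <- junction + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      nuclei <- nuclei + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      junction[junction < 0] <- 0
      nuclei[nuclei < 0] <- 0
    }

    areas <- tabulate(label_map, nbins = n_cells)
    per_cell <- tibble::tibble(
      id = seq_len(n_cells),
      area_um2 = areas * pixel_size^2,
      centroid_x = vapply(seq_len(n_cells), function(i) mean(px[lab == i]), numeric(1)),
      centroid_y = vapply(seq_len(n_cells), function(i) mean(py[lab == i]), numeric(1))
    )

    list(
      junction = intensity_image(junction, pixel_size, "junction"),
      nuclei = intensity_image(nuclei, pixel_size, "nuclei"),
      truth = list(
        label_map = label_map,
        junction_mask = skel,
        band_mask = band,
        dist_to_skeleton = dist_to_skel,
        per_cell = per_cell,
        edges = edges,
        seed_points = seeds,
        intensities = c(J = J, C = C, B = B),
        junction_halfwidth = junction_halfwidth,
        pixel_size = pixel_size
      )
    )
  })
}

#' Derive junction and cytosolic line ROIs from monolayer truth
#'
#' For each pair of adjacent cells with a sufficiently long shared boundary,
#' constructs a straight junction line along the central portion of the
#' shared Voronoi edge plus two parallel cytosolic lines offset into the two
#' neighbouring cells. ROIs whose strokes would leave the junction band
#' (junction line) or touch it (cytosolic lines) are flagged invalid, so
#' downstream intensity ratios sample pure junction and pure cytosol.
#'
#' @param mono Result of [make_monolayer()].
#' @param width_px Stroke width of all three lines (default 15, the standard
#'   width for occludin-type channels).
#' @param cytosol_offset Normal offset of the cytosolic lines from the
#'   junction, px. Default clears the junction band:
#'   `junction_halfwidth + width_px / 2 + 3`.
#' @param trim_frac Fraction of the edge trimmed at each end before placing
#'   the line (avoids tricellular corners).
#' @param min_edge_px Minimum number of shared-boundary pixels for an edge to
#'   be used.
#' @return A tibble with one row per candidate junction: cell ids, the three
#'   [roi_line()] objects (list columns `junction`, `cytosol_a`, `cytosol_b`)
#'   and a `valid` flag.
#' @export
monolayer_junction_rois <- function(mono, width_px = 15,
                                    cytosol_offset = NULL,
                                    trim_frac = 0.25, min_edge_px = 40) {
  truth <- mono$truth
  hw <- truth$junction_halfwidth
  if (is.null(cytosol_offset)) cytosol_offset <- hw + width_px / 2 + 3
  edges <- truth$edges
  if (nrow(edges) == 0L) {
    return(tibble::tibble(cell_a = integer(), cell_b = integer(),
                          junction = list(), cytosol_a = list(),
                          cytosol_b = list(), valid = logical()))
  }
  D <- truth$dist_to_skeleton
  lab <- truth$label_map
  seeds <- truth$seed_points
  dims <- dim(lab)

  grp <- dplyr::group_by(edges, .data$cell_a, .data$cell_b)
  keys <- dplyr::group_keys(grp)
  parts <- dplyr::group_split(grp)

  rows <- purrr::pmap(list(parts, keys$cell_a, keys$cell_b), function(pts, a, b) {
    if (nrow(pts) < min_edge_px) return(NULL)
    u <- c(seeds[b, 1] - seeds[a, 1], seeds[b, 2] - seeds[a, 2])
    nrm <- u / sqrt(sum(u^2))          # unit normal, a -> b
    tang <- c(-nrm[2], nrm[1])         # along the edge
    m <- c(mean(pts$x), mean(pts$y))
    t <- (pts$x - m[1]) * tang[1] + (pts$y - m[2]) * tang[2]
    qs <- stats::quantile(t, c(trim_frac, 1 - trim_frac), names = FALSE)
    if (diff(qs) < 5) return(NULL)
    p0 <- m + qs[1] * tang; p1 <- m + qs[2] * tang
    jline <- roi_line(rbind(p0, p1), width_px)
    ca <- roi_line(rbind(p0 - cytosol_offset * nrm, p1 - cytosol_offset * nrm),
                   width_px)
    cb <- roi_line(rbind(p0 + cytosol_offset * nrm, p1 + cytosol_offset * nrm),
                   width_px)
    ok_line <- function(roi, want_cell = NULL, in_band = FALSE) {
      mk <- stroke_mask(dims, roi)
      if (!any(mk)) return(FALSE)
      # reject strokes clipped by the image boundary
      v <- roi$vertices
      half <- roi$width_px / 2
      if (min(v[, 1]) - half < 0 || max(v[, 1]) + half > dims[2] - 1 ||
          min(v[, 2]) - half < 0 || max(v[, 2]) + half > dims[1] - 1) {
        return(FALSE)
      }
      if (in_band) return(all(D[mk] <= hw))
      all(D[mk] > hw + 0.5) && all(lab[mk] == want_cell)
    }
    valid <- ok_line(jline, in_band = TRUE) && ok_line(ca, a) && ok_line(cb, b)
    tibble::tibble(cell_a = a, cell_b = b, junction = list(jline),
                   cytosol_a = list(ca), cytosol_b = list(cb), valid = valid)
  })
  dplyr::bind_rows(purrr::compact(rows))
}
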