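# Ground-truthed fixtures for morphometry pipelines: elliptical focal
# adhesions, nuclei blobs, and textured bright-field cell islands.

#' Render elliptical focal adhesions with closed-form truth
#'
#' Each ellipse is rendered at its intensity over the background; the truth
#' records the analytic area (pi a b) and maximum Feret diameter
#' (2 max(a, b)) per object, and flags pairs of overlapping ellipses
#' (overlap is not an error, just annotated).
#'
#' @param ellipses Tibble with columns `x_um`, `y_um` (centres), `a_um`,
#'   `b_um` (semi-axes, > 0), `angle_deg`, `intensity`. May have zero rows.
#' @param size Image side in px.
#' @param pixel_size µm/px (default 0.1).
#' @param background Background intensity (default 0).
#' @param noise_sd Additive Gaussian noise sd (default 0).
#' @param seed RNG seed.
#' @return List with `image` ([intensity_image()]) and `truth` tibble
#'   (`id`, `area_um2`, `max_feret_um`, `overlapping`).
#' @export
make_adhesion_image <- function(ellipses, size = 256L, pixel_size = 0.1,
                                background = 0, noise_sd = 0, seed = 1L) {
  n <- nrow(ellipses)
  if (n > 0 && any(ellipses$a_um <= 0 | ellipses$b_um <= 0)) {
    stop("semi-axes must be > 0", call. = FALSE)
  }
  local_seed(seed, {
    nr <- nc <- as.integer(size)
    px <- rep(seq_len(nc) - 1, each = nr) * pixel_size
    py <- rep(seq_len(nr) - 1, times = nc) * pixel_size
    img <- matrix(background, nr, nc)
    cover <- matrix(0L, nr, nc)
    for (i in seq_len(n)) {
      th <- ellipses$angle_deg[i] * pi / 180
      dx <- px - ellipses$x_um[i]; dy <- py - ellipses$y_um[i]
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      inside <- (u / ellipses$a_um[i])^2 + (v / ellipses$b_um[i])^2 <= 1
      m <- matrix(inside, nr, nc)
      img[m] <- pmax(img[m], ellipses$intensity[i])
      cover <- cover + m
    }
    if (noise_sd > 0) {
      img <- pmax(img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
    }
    truth <- if (n > 0) {
      tibble::tibble(
        id = seq_len(n),
        area_um2 = pi * ellipses$a_um * ellipses$b_um,
        max_feret_um = 2 * pmax(ellipses$a_um, ellipses$b_um),
        overlapping = vapply(seq_len(n), function(i) {
          th <- ellipses$angle_deg[i] * pi / 180
          dx <- px - ellipses$x_um[i]; dy <- py - ellipses$y_um[i]
          u <- dx * cos(th) + dy * sin(th)
          v <- -dx * sin(th) + dy * cos(th)
          inside <- (u / ellipses$a_um[i])^2 + (v / ellipses$b_um[i])^2 <= 1
          any(cover[matrix(inside, nr, nc)] > 1L)
        }, logical(1))
      )
    } else {
      tibble::tibble(id = integer(), area_um2 = numeric(),
                     max_feret_um = numeric(), overlapping = logical())
    }
    list(image = intensity_image(img, pixel_size, "adhesions"), truth = truth)
  })
}

#' Render nuclei as bright disks with soft edges
#'
#' @param centres An n x 2 matrix of (x, y) centres in px, or `NULL` to place
#'   `n` nuclei at random with minimum separation `2.5 * radius_px`.
#' @param n Number of nuclei when `centres` is `NULL`.
#' @param radius_px Nucleus radius in px (default 8).
#' @param size Image side in px.
#' @param pixel_size µm/px.
#' @param intensity Peak intensity (default 200).
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return List with `image` and `truth` (list: `centres`, `count`).
#' @export
make_nuclei_image <- function(centres = NULL, n = 20L, radius_px = 8,
                              size = 512L, pixel_size = 0.26,
                              intensity = 200, noise_sd = 0, seed = 1L) {
  local_seed(seed, {
    nr <- nc <- as.integer(size)
    if (is.null(centres)) {
      centres <- matrix(numeric(0), 0, 2)
      margin <- 2 * radius_px
      tries <- 0L
      while (nrow(centres) < n && tries < 20000L) {
        tries <- tries + 1L
        cand <- c(stats::runif(1, margin, nc - 1 - margin),
                  stats::runif(1, margin, nr - 1 - margin))
        if (nrow(centres) == 0L ||
            all((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2 >
                  (2.5 * radius_px)^2)) {
          centres <- rbind(centres, cand)
        }
      }
      if (nrow(centres) < n) {
        stop("could not place all nuclei without overlap; reduce n or radius",
             call. = FALSE)
      }
    } else {
      centres <- as.matrix(centres)
    }
    px <- rep(seq_len(nc) - 1, each = nr)
    py <- rep(seq_len(nr) - 1, times = nc)
    img <- matrix(0, nr, nc)
    edge <- radius_px / 4  # soft shoulder
    for (i in seq_len(nrow(centres))) {
      d <- sqrt((px - centres[i, 1])^2 + (py - centres[i, 2])^2)
      prof <- pmin(1, pmax(0, (radius_px - d) / edge + 1))
      img <- pmax(img, matrix(intensity * prof, nr, nc))
    }
    if (noise_sd > 0) {
      img <- pmax(img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
    }
    list(image = intensity_image(img, pixel_size, "nuclei"),
         truth = list(centres = centres, count = nrow(centres)))
  })
}

#' Render a textured bright-field island field with ground-truth mask
#'
#' Cell islands appear in bright-field as textured regions over a smooth
#' background. Shapes (discs and axis-aligned rectangles, e.g. bridges
#' merging two discs) are unioned into the truth mask; texture is uniform
#' speckle added inside the mask.
#'
#' @param shapes Tibble with columns `type` (`"disc"` or `"rect"`) and
#'   geometry columns: discs use `x`, `y`, `r` (px); rects use `x0`, `y0`,
#'   `x1`, `y1` (px).
#' @param size Image side in px.
#' @param pixel_size µm/px (default 0.65, a 10x bright-field objective).
#' @param background Background level (default 100).
#' @param texture_amp Peak-to-peak amplitude of the island speckle texture
#'   (default 80).
#' @param background_noise_sd Gaussian noise on the background (default 1).
#' @param seed RNG seed.
#' @return List with `image` ([intensity_image()]) and `truth` (list:
#'   `mask`, `coverage_percent`, `n_islands`, `island_areas_um2`).
#' @export
make_island_field <- function(shapes, size = 1000L, pixel_size = 0.65,
                              background = 100, texture_amp = 80,
                              background_noise_sd = 1, seed = 1L) {
  local_seed(seed, {
    nr <- nc <- as.integer(size)
    px <- rep(seq_len(nc) - 1, each = nr)
    py <- rep(seq_len(nr) - 1, times = nc)
    mask <- matrix(FALSE, nr, nc)
    for (i in seq_len(nrow(shapes))) {
      m <- if (shapes$type[i] == "disc") {
        (px - shapes$x[i])^2 + (py - shapes$y[i])^2 <= shapes$r[i]^2
      } else if (shapes$type[i] == "rect") {
        px >= shapes$x0[i] & px <= shapes$x1[i] &
          py >= shapes$y0[i] & py <= shapes$y1[i]
      } else {
        stop("unknown shape type: ", shapes$type[i], call. = FALSE)
      }
      mask <- mask | matrix(m, nr, nc)
    }
    img <- matrix(background, nr, nc)
    if (background_noise_sd > 0) {
      img <- img + matrix(stats::rnorm(nr * nc, 0, background_noise_sd), nr, nc)
    }
    n_in <- sum(mask)
    if (n_in > 0) {
      img[mask] <- img[mask] + texture_amp * (stats::runif(n_in) - 0.5)
    }
    img <- pmax(img, 0)
    comp <- EBImage::bwlabel(EBImage::Image(mask * 1))
    labels <- matrix(as.integer(comp), nr, nc)
    areas <- tabulate(labels) * pixel_size^2
    list(
      image = intensity_image(img, pixel_size, "brightfield"),
      truth = list(mask = mask,
                   coverage_percent = 100 * n_in / (nr * nc),
                   n_islands = max(labels),
                   island_areas_um2 = areas)
    )
  })
}
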