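# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

gblur_matrix <- function(m, sigma) {
  as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma)))
}

checkerboard <- function(n = 64L) {
  m <- matrix(0, n, n)
  m[(row(m) + col(m)) %% 2 == 0] <- 1
  m
}

# Rectangle polygon whose interior contains exactly the pixels with centres
# x in [x0, x1] and y in [y0, y1] (integer pixel coordinates).
pixel_rect <- function(x0, x1, y0, y1) {
  roi_region(rbind(c(x0 - 0.5, y0 - 0.5), c(x1 + 0.5, y0 - 0.5),
                   c(x1 + 0.5, y1 + 0.5), c(x0 - 0.5, y1 + 0.5)))
}

# Standard 5-disc island layout: five non-overlapping, non-border discs
# jointly covering 30% of a 1000 x 1000 px field.
five_disc_shapes <- function() {
  r <- sqrt(0.3 * 1000^2 / 5 / pi)
  tibble::tibble(type = "disc",
                 x = c(170, 500, 830, 250, 650),
                 y = c(170, 170, 170, 650, 700),
                 r = r)
}

# A small dipole TFM fixture reused across tests.
dipole_pair <- function(seed = 1L, loc_noise_px = 0) {
  make_tfm_pair(tfm_dipole_spots(c(40, 40)), seed = seed,
                loc_noise_px = loc_noise_px)
}

# Independent geometric oracle: given grid lines (point + direction), count
# the distinct strands whose segments straddle each infinite line, using a
# direct parametric segment-line intersection (solved as a 2x2 linear
# system, unlike the implementation's signed-side test).
oracle_counts <- function(net, grid) {
  vapply(seq_len(nrow(grid)), function(i) {
    p <- c(grid$px[i], grid$py[i]); d <- c(grid$nx[i], grid$ny[i])
    hit <- vapply(net$strands, function(st) {
      for (seg in st$segments) {
        for (k in seq_len(nrow(seg) - 1L)) {
          a <- seg[k, ]; b <- seg[k + 1L, ]
          A <- cbind(b - a, -d)
          if (abs(det(A)) < 1e-12) next
          sol <- solve(A, p - a)
          if (sol[1] >= 0 && sol[1] <= 1) return(TRUE)
        }
      }
      FALSE
    }, logical(1))
    sum(hit)
  }, integer(1))
}
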