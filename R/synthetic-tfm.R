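# Ground-truthed synthetic traction force microscopy fixtures: a traction
# field of Gaussian spots is pushed through the forward Boussinesq model to
# displace a random bead field, and the rendered stressed/relaxed image pair
# is returned together with the full generative truth. The forward model is
# the independent oracle for the FTTC inversion.

#' Gaussian traction spot table
#'
#' Convenience constructor for the spot specification consumed by
#' [make_tfm_pair()].
#'
#' @param x_um,y_um Spot centres in µm.
#' @param amp_pa Peak traction amplitudes in Pa.
#' @param sigma_um Gaussian widths in µm.
#' @param dir_deg Traction directions in degrees (0 = +x, 90 = +y).
#' @return A tibble of spot parameters.
#' @export
traction_spots <- function(x_um, y_um, amp_pa, sigma_um, dir_deg) {
  tibble::tibble(x_um = x_um, y_um = y_um, amp_pa = amp_pa,
                 sigma_um = sigma_um, dir_deg = dir_deg)
}

#' Balanced contractile dipole spot pair
#'
#' Two equal and opposite inward-pointing traction spots, the canonical
#' zero-net-force island fixture.
#'
#' @param centre_um Centre of the dipole (length-2, µm).
#' @param separation_um Distance between the two spots, µm.
#' @param amp_pa Peak amplitude, Pa.
#' @param sigma_um Spot width, µm.
#' @return A two-row spot tibble for [make_tfm_pair()].
#' @export
tfm_dipole_spots <- function(centre_um, separation_um = 16, amp_pa = 300,
                             sigma_um = 4) {
  half <- separation_um / 2
  traction_spots(
    x_um = centre_um[1] + c(-half, half),
    y_um = centre_um[2] + c(0, 0),
    amp_pa = c(amp_pa, amp_pa),
    sigma_um = c(sigma_um, sigma_um),
    dir_deg = c(0, 180)  # both point inward: net force zero
  )
}

# Rasterise Gaussian traction spots on a square grid of spacing h over
# [0, extent) µm. Returns tx, ty matrices (rows = y).
render_traction <- function(spots, extent_um, h) {
  n <- max(2L, round(extent_um / h))
  xs <- (seq_len(n) - 1) * h
  GX <- matrix(xs, n, n, byrow = TRUE)
  GY <- matrix(xs, n, n)
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  for (i in seq_len(nrow(spots))) {
    g <- spots$amp_pa[i] * exp(-((GX - spots$x_um[i])^2 +
                                   (GY - spots$y_um[i])^2) /
                                 (2 * spots$sigma_um[i]^2))
    th <- spots$dir_deg[i] * pi / 180
    tx <- tx + g * cos(th)
    ty <- ty + g * sin(th)
  }
  list(tx = tx, ty = ty)
}

# Add a Gaussian PSF spot of sd `sigma` px at each (x, y) px onto `img`.
render_beads <- function(img, x, y, sigma = 1, amplitude = 1, r = 4L) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- -r:r
  for (k in seq_along(x)) {
    cj <- round(x[k]) ; ci <- round(y[k])
    jj <- (cj + offs); ii <- (ci + offs)
    keep_j <- jj >= 0 & jj <= nc - 1
    keep_i <- ii >= 0 & ii <= nr - 1
    if (!any(keep_i) || !any(keep_j)) next
    jj <- jj[keep_j]; ii <- ii[keep_i]
    gx <- exp(-(jj - x[k])^2 / (2 * sigma^2))
    gy <- exp(-(ii - y[k])^2 / (2 * sigma^2))
    img[ii + 1L, jj + 1L] <- img[ii + 1L, jj + 1L] +
      amplitude * outer(gy, gx)
  }
  img
}

#' Generate a synthetic bead image pair with full TFM ground truth
#'
#' The traction field defined by `spots` is rasterised on the pixel grid and
#' pushed through the forward Boussinesq model ([tfm_forward()], factor-2
#' zero padding, zero-mean displacement) to obtain the true displacement
#' field. Beads are placed uniformly at random, rendered as Gaussian PSF
#' spots (sd 1 px: the 0.20 µm beads are below the diffraction limit, so the
#' PSF sets the spot size) in their relaxed positions and in positions
#' displaced by the interpolated displacement, with optional per-bead
#' localisation noise. The true strain energy `U = 1/2 sum(T . u) h_px^2` is
#' recorded along with the fields sampled on the analysis grid and a circular
#' island polygon enclosing the spots.
#'
#' @param spots Spot tibble (see [traction_spots()]).
#' @param E Young's modulus, Pa (default 16400, the mean stiffness of the
#'   TFM gels).
#' @param nu Poisson ratio (default 0.5, incompressible polyacrylamide).
#' @param extent_um Side of the square field of view, µm (default 80).
#' @param pixel_size µm/px of the bead images (default 0.2).
#' @param grid_h Analysis grid spacing, µm (default 2.6).
#' @param bead_density Beads per µm² (default 1).
#' @param bead_sigma_px Gaussian PSF sd, px (default 1).
#' @param loc_noise_px Gaussian localisation noise added to the stressed bead
#'   positions, px (default 0).
#' @param island_margin_um Margin added to the island circle radius beyond
#'   the spot 3-sigma extent (default 5).
#' @param seed RNG seed.
#' @return List with `stressed`, `relaxed` ([intensity_image()]) and `truth`
#'   (list: `traction`, `displacement` on the analysis grid, `U_true_J`,
#'   `island`, `density_true_J_per_um2`, bead positions, substrate
#'   parameters).
#' @export
make_tfm_pair <- function(spots, E = 16400, nu = 0.5, extent_um = 80,
                          pixel_size = 0.2, grid_h = 2.6, bead_density = 1,
                          bead_sigma_px = 1, loc_noise_px = 0,
                          island_margin_um = 5, seed = 1L) {
  if (nu < 0 || nu > 0.5) stop("`nu` must be in [0, 0.5]", call. = FALSE)
  if (E <= 0) stop("`E` must be > 0", call. = FALSE)
  local_seed(seed, {
    npix <- round(extent_um / pixel_size)
    tr_fine <- render_traction(spots, extent_um, pixel_size)
    t_field_fine <- traction_field(tr_fine$tx, tr_fine$ty, pixel_size, E, nu)
    u_fine <- tfm_forward(t_field_fine, pad = 2L)
    U_pa_um3 <- 0.5 * sum(tr_fine$tx * u_fine$ux + tr_fine$ty * u_fine$uy) *
      pixel_size^2
    U_J <- U_pa_um3 * 1e-18

    # island polygon: circle enclosing all spots to 3 sigma plus margin
    cx <- mean(spots$x_um); cy <- mean(spots$y_um)
    rad <- max(sqrt((spots$x_um - cx)^2 + (spots$y_um - cy)^2) +
                 3 * spots$sigma_um) + island_margin_um
    th <- seq(0, 2 * pi, length.out = 97L)[-97L]
    island <- roi_region(cbind(cx + rad * cos(th), cy + rad * sin(th)))

    # truth fields sampled on the analysis grid
    gn <- floor((npix - 1) * pixel_size / grid_h) + 1L
    gpx <- (seq_len(gn) - 1) * grid_h / pixel_size  # grid nodes in px coords
    GX <- rep(gpx, each = gn); GY <- rep(gpx, times = gn)
    samp <- function(m) matrix(bilinear_sample(m, GX, GY), gn, gn)
    truth_u <- displacement_field(samp(u_fine$ux), samp(u_fine$uy), grid_h)
    truth_t <- traction_field(samp(tr_fine$tx), samp(tr_fine$ty), grid_h, E, nu)

    n_beads <- round(bead_density * extent_um^2)
    bx <- stats::runif(n_beads, 0, npix - 1)
    by <- stats::runif(n_beads, 0, npix - 1)
    ubx <- bilinear_sample(u_fine$ux, bx, by) / pixel_size  # px
    uby <- bilinear_sample(u_fine$uy, bx, by) / pixel_size
    sx <- bx + ubx; sy <- by + uby
    if (loc_noise_px > 0) {
      sx <- sx + stats::rnorm(n_beads, 0, loc_noise_px)
      sy <- sy + stats::rnorm(n_beads, 0, loc_noise_px)
    }
    relaxed <- render_beads(matrix(0, npix, npix), bx, by, bead_sigma_px)
    stressed <- render_beads(matrix(0, npix, npix), sx, sy, bead_sigma_px)

    area <- polygon_area(island$polygon)
    list(
      stressed = intensity_image(stressed, pixel_size, "beads_stressed"),
      relaxed = intensity_image(relaxed, pixel_size, "beads_relaxed"),
      truth = list(
        traction = truth_t,
        displacement = truth_u,
        U_true_J = U_J,
        island = island,
        island_area_um2 = area,
        density_true_J_per_um2 = U_J / area,
        bead_relaxed_px = cbind(x = bx, y = by),
        bead_stressed_px = cbind(x = sx, y = sy),
        E = E, nu = nu, pixel_size = pixel_size, grid_h = grid_h
      )
    )
  })
}
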