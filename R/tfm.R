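# Traction force microscopy: drift registration, displacement estimation from
# bead image pairs, unconstrained Fourier-transform traction cytometry (FTTC),
# strain energy, and the island-level equilibrium filter and normalisation.
#
# Vector fields live on a regular square lattice of spacing `h` (µm, default
# 2.6); node (i, j) of the matrices sits at (x, y) = ((j-1) h, (i-1) h).
# Displacements are in µm, tractions in Pa. The substrate is an elastic
# half-space with Young's modulus E (Pa) and Poisson ratio nu; in Fourier
# space displacement and traction are linked per wavevector k by the
# Boussinesq Green tensor
#   G(k) = (2 (1+nu) / (E k^3)) * [ (1-nu) k^2 + nu ky^2,  -nu kx ky ;
#                                   -nu kx ky,  (1-nu) k^2 + nu kx^2 ].

#' Regular-grid displacement field
#'
#' @param ux,uy Matrices of x/y displacement components (µm), rows = y.
#' @param h Grid spacing in µm (> 0).
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(ux, uy, h) {
  ux <- as.matrix(ux); uy <- as.matrix(uy)
  stopifnot(identical(dim(ux), dim(uy)))
  if (!is.numeric(h) || h <= 0) stop("`h` must be > 0", call. = FALSE)
  if (!all(is.finite(ux)) || !all(is.finite(uy))) {
    stop("displacement values must be finite", call. = FALSE)
  }
  structure(list(ux = ux, uy = uy, h = as.numeric(h)),
            class = "displacement_field")
}

#' Regular-grid traction field
#'
#' @param tx,ty Matrices of x/y traction components (Pa), rows = y.
#' @param h Grid spacing in µm.
#' @param E Substrate Young's modulus (Pa, > 0).
#' @param nu Substrate Poisson ratio in [0, 0.5].
#' @return Object of class `traction_field`.
#' @export
traction_field <- function(tx, ty, h, E, nu = 0.5) {
  tx <- as.matrix(tx); ty <- as.matrix(ty)
  stopifnot(identical(dim(tx), dim(ty)))
  if (E <= 0) stop("`E` must be > 0", call. = FALSE)
  if (nu < 0 || nu > 0.5) stop("`nu` must be in [0, 0.5]", call. = FALSE)
  if (!all(is.finite(tx)) || !all(is.finite(ty))) {
    stop("traction values must be finite", call. = FALSE)
  }
  structure(list(tx = tx, ty = ty, h = as.numeric(h), E = as.numeric(E),
                 nu = as.numeric(nu)),
            class = "traction_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %d x %d nodes, h = %.3g um, max |u| = %.3g um\n",
              nrow(x$ux), ncol(x$ux), x$h, max(sqrt(x$ux^2 + x$uy^2))))
  invisible(x)
}

#' @export
print.traction_field <- function(x, ...) {
  cat(sprintf("<traction_field> %d x %d nodes, h = %.3g um, E = %.3g Pa, nu = %.2f, max |T| = %.3g Pa\n",
              nrow(x$tx), ncol(x$tx), x$h, x$E, x$nu, max(sqrt(x$tx^2 + x$ty^2))))
  invisible(x)
}

# Angular wavenumbers for an n-point axis of spacing h.
fft_wavenumbers <- function(n, h) {
  f <- c(seq(0, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1)) / (n * h)
  2 * pi * f
}

# Elementwise Boussinesq kernel components on the (ky, kx) grid.
boussinesq_kernel <- function(nr, nc, h, E, nu) {
  kx <- fft_wavenumbers(nc, h)
  ky <- fft_wavenumbers(nr, h)
  KX <- matrix(kx, nr, nc, byrow = TRUE)
  KY <- matrix(ky, nr, nc)
  K2 <- KX^2 + KY^2
  K <- sqrt(K2)
  K[1, 1] <- Inf  # zero mode handled separately
  pref <- 2 * (1 + nu) / (E * K^3)
  list(
    g11 = pref * ((1 - nu) * K2 + nu * KY^2),
    g12 = -pref * nu * KX * KY,
    g22 = pref * ((1 - nu) * K2 + nu * KX^2)
  )
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) Re(stats::fft(m, inverse = TRUE)) / length(m)

#' Forward elastic model: displacement generated by a traction field
#'
#' Applies the Boussinesq half-space Green tensor in Fourier space,
#' `u_hat(k) = G(k) T_hat(k)`, with the zero-frequency mode set to zero (no
#' rigid translation). The traction is zero-padded by `pad` before the FFT;
#' padding is exact for compactly supported tractions and suppresses periodic
#' wrap-around.
#'
#' @param traction A [traction_field()].
#' @param pad Integer padding factor (>= 1, default 2).
#' @param crop If `TRUE` (default) return the displacement on the original
#'   grid; otherwise on the full padded grid.
#' @return A [displacement_field()].
#' @export
tfm_forward <- function(traction, pad = 2L, crop = TRUE) {
  stopifnot(inherits(traction, "traction_field"))
  nr <- nrow(traction$tx); nc <- ncol(traction$tx)
  npr <- nr * pad; npc <- nc * pad
  tx <- matrix(0, npr, npc); ty <- matrix(0, npr, npc)
  tx[seq_len(nr), seq_len(nc)] <- traction$tx
  ty[seq_len(nr), seq_len(nc)] <- traction$ty
  g <- boussinesq_kernel(npr, npc, traction$h, traction$E, traction$nu)
  thx <- fft2(tx); thy <- fft2(ty)
  uhx <- g$g11 * thx + g$g12 * thy
  uhy <- g$g12 * thx + g$g22 * thy
  uhx[1, 1] <- 0; uhy[1, 1] <- 0
  ux <- ifft2(uhx); uy <- ifft2(uhy)
  if (crop) {
    ux <- ux[seq_len(nr), seq_len(nc)]
    uy <- uy[seq_len(nr), seq_len(nc)]
  }
  displacement_field(ux, uy, traction$h)
}

#' Unconstrained Fourier-transform traction cytometry
#'
#' Inverts the Boussinesq relation per nonzero wavevector,
#' `T_hat(k) = G(k)^{-1} u_hat(k)`, with the zero-frequency traction set to
#' zero. No regularisation is applied (unconstrained inversion); an optional
#' Hann window and zero-padding are available to control spectral leakage on
#' noisy experimental fields and are off by default so that the inversion is
#' the exact inverse of [tfm_forward()] on a shared grid.
#'
#' @param u A [displacement_field()].
#' @param E Young's modulus in Pa.
#' @param nu Poisson ratio in [0, 0.5] (default 0.5, incompressible gel).
#' @param pad Integer padding factor (default 1, none).
#' @param hann Apply a Hann window before the FFT (default `FALSE`).
#' @return A [traction_field()] on the grid of `u`.
#' @export
fttc <- function(u, E, nu = 0.5, pad = 1L, hann = FALSE) {
  stopifnot(inherits(u, "displacement_field"))
  if (E <= 0) stop("`E` must be > 0", call. = FALSE)
  if (nu < 0 || nu > 0.5) stop("`nu` must be in [0, 0.5]", call. = FALSE)
  nr <- nrow(u$ux); nc <- ncol(u$ux)
  ux <- u$ux - mean(u$ux); uy <- u$uy - mean(u$uy)
  if (hann) {
    wr <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))
    wc <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
    W <- outer(wr, wc)
    ux <- ux * W; uy <- uy * W
  }
  npr <- nr * pad; npc <- nc * pad
  if (pad > 1L) {
    z <- matrix(0, npr, npc)
    zx <- z; zx[seq_len(nr), seq_len(nc)] <- ux
    zy <- z; zy[seq_len(nr), seq_len(nc)] <- uy
    ux <- zx; uy <- zy
  }
  g <- boussinesq_kernel(npr, npc, u$h, E, nu)
  uhx <- fft2(ux); uhy <- fft2(uy)
  det <- g$g11 * g$g22 - g$g12^2
  thx <- (g$g22 * uhx - g$g12 * uhy) / det
  thy <- (-g$g12 * uhx + g$g11 * uhy) / det
  thx[1, 1] <- 0; thy[1, 1] <- 0
  tx <- ifft2(thx)[seq_len(nr), seq_len(nc)]
  ty <- ifft2(thy)[seq_len(nr), seq_len(nc)]
  traction_field(tx, ty, u$h, E, nu)
}

# ---- drift registration -----------------------------------------------------

# Cross-correlation peak with 3-point parabolic subpixel refinement along
# each axis. `cc` is a correlation matrix whose [1,1] element is zero lag.
cc_peak_subpixel <- function(cc) {
  nr <- nrow(cc); nc <- ncol(cc)
  idx <- which.max(cc)
  pi_ <- (idx - 1L) %% nr + 1L
  pj <- (idx - 1L) %/% nr + 1L
  wrap <- function(i, n) ifelse(i > n / 2, i - 1L - n, i - 1L)
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den == 0) 0 else 0.5 * (cm - cp) / den
  }
  im <- (pi_ - 2L) %% nr + 1L; ip <- pi_ %% nr + 1L
  jm <- (pj - 2L) %% nc + 1L; jp <- pj %% nc + 1L
  dy <- wrap(pi_, nr) + refine(cc[im, pj], cc[pi_, pj], cc[ip, pj])
  dx <- wrap(pj, nc) + refine(cc[pi_, jm], cc[pi_, pj], cc[pi_, jp])
  list(dx = dx, dy = dy, peak = cc[pi_, pj])
}

# Bilinear sample of matrix `m` at pixel coordinates (x, y); outside values
# are clamped to the border.
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  j0 <- pmin(floor(x), nc - 2); i0 <- pmin(floor(y), nr - 2)
  fx <- x - j0; fy <- y - i0
  i0 <- i0 + 1L; j0 <- j0 + 1L
  m[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    m[cbind(i0, j0 + 1L)] * fx * (1 - fy) +
    m[cbind(i0 + 1L, j0)] * (1 - fx) * fy +
    m[cbind(i0 + 1L, j0 + 1L)] * fx * fy
}

#' Estimate and correct rigid drift between a bead image pair
#'
#' Estimates the rigid translation from the relaxed to the stressed frame by
#' normalised cross-correlation with parabolic subpixel peak refinement, and
#' resamples the relaxed image onto the stressed frame.
#'
#' @param stressed,relaxed [intensity_image()] bead images.
#' @param min_correlation Normalised correlation floor below which
#'   registration is considered failed (default 0.2).
#' @return A list with `dx`, `dy` (drift in px, stressed relative to
#'   relaxed), `correlation`, and `relaxed_registered` (an
#'   [intensity_image()]).
#' @export
register_drift <- function(stressed, relaxed, min_correlation = 0.2) {
  stopifnot(inherits(stressed, "intensity_image"),
            inherits(relaxed, "intensity_image"))
  a <- stressed$pixels; b <- relaxed$pixels
  stopifnot(identical(dim(a), dim(b)))
  a0 <- a - mean(a); b0 <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(a0) * Conj(stats::fft(b0)), inverse = TRUE)) /
    length(a0)
  norm <- sqrt(sum(a0^2) * sum(b0^2))
  pk <- cc_peak_subpixel(cc / norm)
  if (!is.finite(pk$peak) || pk$peak < min_correlation) {
    stop("drift registration failed: correlation peak below floor",
         call. = FALSE)
  }
  # stressed(x) ~ relaxed(x - d): shift relaxed by d with an exact Fourier
  # phase shift (bead spots are smooth, so spectral interpolation is
  # essentially exact; periodic wrap only touches the border)
  nr <- nrow(b); nc <- ncol(b)
  kx <- fft_wavenumbers(nc, 1)
  ky <- fft_wavenumbers(nr, 1)
  phase <- exp(-1i * (outer(rep(1, nr), kx * pk$dx) +
                        outer(ky * pk$dy, rep(1, nc))))
  reg <- Re(stats::fft(stats::fft(b) * phase, inverse = TRUE)) / length(b)
  list(dx = pk$dx, dy = pk$dy, correlation = pk$peak,
       relaxed_registered = intensity_image(pmax(reg, 0), relaxed$pixel_size,
                                            relaxed$channel))
}

# ---- bead detection and PIV -------------------------------------------------

# Detect bead spots as local maxima above `thresh` x image max, refined by
# centre of mass in a (2r+1)^2 window. Returns an n x 2 matrix (x, y) px.
detect_beads <- function(pixels, thresh = 0.15, r = 2L) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  floorv <- thresh * max(pixels)
  inner <- pixels[2:(nr - 1), 2:(nc - 1)]
  is_max <- inner >= floorv
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pixels[2:(nr - 1) + di, 2:(nc - 1) + dj]
    is_max <- is_max & (inner >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 2))
  ci <- idx[, 1] + 1L; cj <- idx[, 2] + 1L
  xs <- numeric(nrow(idx)); ys <- numeric(nrow(idx))
  offs <- -r:r
  for (k in seq_len(nrow(idx))) {
    ii <- pmin(pmax(ci[k] + offs, 1L), nr)
    jj <- pmin(pmax(cj[k] + offs, 1L), nc)
    w <- pixels[ii, jj]
    w <- w - min(w)
    s <- sum(w)
    if (s <= 0) { xs[k] <- cj[k] - 1; ys[k] <- ci[k] - 1; next }
    xs[k] <- sum(rep(jj - 1, each = length(ii)) * w) / s
    ys[k] <- sum(rep(ii - 1, times = length(jj)) * w) / s
  }
  cbind(x = xs, y = ys)
}

# Coarse PIV: cross-correlate interrogation windows, subpixel peak. Returns a
# list with window-centre coordinates (px) and displacements (px).
piv_windows <- function(a, b, window = 32L, overlap = 0.5) {
  nr <- nrow(a); nc <- ncol(a)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  ys <- seq(1L, nr - window + 1L, by = step)
  xs <- seq(1L, nc - window + 1L, by = step)
  cx <- matrix(NA_real_, length(ys), length(xs))
  cy <- cx; ux <- cx; uy <- cx
  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      ra <- a[ys[iy]:(ys[iy] + window - 1L), xs[ix]:(xs[ix] + window - 1L)]
      rb <- b[ys[iy]:(ys[iy] + window - 1L), xs[ix]:(xs[ix] + window - 1L)]
      ra <- ra - mean(ra); rb <- rb - mean(rb)
      if (sum(ra^2) == 0 || sum(rb^2) == 0) next
      cc <- Re(stats::fft(stats::fft(ra) * Conj(stats::fft(rb)),
                          inverse = TRUE)) / length(ra)
      pk <- cc_peak_subpixel(cc)
      ux[iy, ix] <- pk$dx; uy[iy, ix] <- pk$dy
      cx[iy, ix] <- xs[ix] - 1 + (window - 1) / 2
      cy[iy, ix] <- ys[iy] - 1 + (window - 1) / 2
    }
  }
  list(cx = cx, cy = cy, ux = ux, uy = uy,
       x0 = xs[1] - 1 + (window - 1) / 2, y0 = ys[1] - 1 + (window - 1) / 2,
       step = step)
}

# Bilinear lookup on the PIV window grid at pixel positions (x, y).
piv_lookup <- function(piv, x, y) {
  gx <- (x - piv$x0) / piv$step
  gy <- (y - piv$y0) / piv$step
  list(ux = bilinear_sample(piv$ux, gx, gy), uy = bilinear_sample(piv$uy, gx, gy))
}

#' Displacement field from a drift-corrected bead image pair
#'
#' Coarse particle image velocimetry (cross-correlation of interrogation
#' windows with subpixel peak refinement) seeds per-bead tracking
#' (nearest-neighbour matching within a search radius around the
#' PIV-predicted position). The scattered bead displacements are then
#' interpolated onto a regular output grid of spacing `h` µm by local
#' weighted linear (plane) fits; grid nodes with too few beads fall back to
#' the PIV estimate.
#'
#' @param stressed,relaxed [intensity_image()] bead images on the same frame
#'   (register first with [register_drift()]).
#' @param h Output grid spacing in µm (default 2.6).
#' @param window PIV interrogation window in px (default 32).
#' @param overlap PIV window overlap fraction (default 0.5).
#' @param search_radius Bead-matching search radius around the PIV-predicted
#'   position, px (default 3).
#' @param track_beads Refine PIV with bead tracking (default `TRUE`).
#' @param min_beads Minimum matched beads for a local plane fit (default 6).
#' @param fit_sigma Gaussian weight sd of the local plane fit, µm (default
#'   `0.75 * h`: narrow enough not to flatten traction peaks, wide enough
#'   not to pass per-bead localisation noise into the unconstrained
#'   inversion, which amplifies high-frequency error).
#' @param fit_radius Bead-inclusion radius of the local fit, µm (default
#'   `2 * h`).
#' @return A [displacement_field()] (µm). Attribute `n_beads` records the
#'   number of matched beads. Warns when bead coverage is sparse.
#' @export
estimate_displacement_field <- function(stressed, relaxed, h = 2.6,
                                        window = 32L, overlap = 0.5,
                                        search_radius = 3,
                                        track_beads = TRUE, min_beads = 6L,
                                        fit_sigma = 0.75 * h,
                                        fit_radius = 2 * h) {
  stopifnot(inherits(stressed, "intensity_image"),
            inherits(relaxed, "intensity_image"))
  a <- stressed$pixels; b <- relaxed$pixels
  stopifnot(identical(dim(a), dim(b)))
  ps <- stressed$pixel_size
  if (max(a) == min(a) || max(b) == min(b)) {
    stop("empty bead images: no displacement field can be estimated",
         call. = FALSE)
  }
  piv <- piv_windows(a, b, window = window, overlap = overlap)
  nr <- nrow(a); nc <- ncol(a)
  gn_c <- max(2L, floor((nc - 1) * ps / h) + 1L)
  gn_r <- max(2L, floor((nr - 1) * ps / h) + 1L)
  gxs <- (seq_len(gn_c) - 1) * h / ps  # node positions in px
  gys <- (seq_len(gn_r) - 1) * h / ps

  beads <- NULL
  if (track_beads) {
    pb <- detect_beads(b)
    pa <- detect_beads(a)
    n_windows <- sum(is.finite(piv$ux))
    if (nrow(pb) < 4L * max(1L, n_windows)) {
      warning("sparse bead field: fewer than 4 beads per interrogation window",
              call. = FALSE)
    }
    if (nrow(pb) > 0L && nrow(pa) > 0L) {
      pred <- piv_lookup(piv, pb[, 1], pb[, 2])
      tx <- pb[, 1] + pred$ux; ty <- pb[, 2] + pred$uy
      # bucket stressed beads on an integer grid for fast neighbour lookup
      cell <- max(1, ceiling(search_radius))
      key <- function(x, y) paste(floor(x / cell), floor(y / cell))
      buckets <- split(seq_len(nrow(pa)), key(pa[, 1], pa[, 2]))
      mx <- rep(NA_real_, nrow(pb)); my <- rep(NA_real_, nrow(pb))
      for (k in seq_len(nrow(pb))) {
        cands <- integer(0)
        bx <- floor(tx[k] / cell); by <- floor(ty[k] / cell)
        for (dx in -1:1) for (dy in -1:1) {
          cands <- c(cands, buckets[[paste(bx + dx, by + dy)]])
        }
        if (length(cands) == 0L) next
        d2 <- (pa[cands, 1] - tx[k])^2 + (pa[cands, 2] - ty[k])^2
        jmin <- which.min(d2)
        if (d2[jmin] <= search_radius^2) {
          mx[k] <- pa[cands[jmin], 1]; my[k] <- pa[cands[jmin], 2]
        }
      }
      ok <- is.finite(mx)
      if (sum(ok) >= min_beads) {
        beads <- list(x = pb[ok, 1], y = pb[ok, 2],
                      ux = mx[ok] - pb[ok, 1], uy = my[ok] - pb[ok, 2])
      }
    }
  }

  ux <- matrix(0, gn_r, gn_c); uy <- matrix(0, gn_r, gn_c)
  fit_radius <- fit_radius / ps
  for (iy in seq_len(gn_r)) {
    for (ix in seq_len(gn_c)) {
      done <- FALSE
      if (!is.null(beads)) {
        dx <- beads$x - gxs[ix]; dy <- beads$y - gys[iy]
        d2 <- dx * dx + dy * dy
        sel <- d2 <= fit_radius^2
        if (sum(sel) >= min_beads) {
          w <- exp(-d2[sel] / (2 * (fit_sigma / ps)^2))
          X <- cbind(1, dx[sel], dy[sel])
          XtW <- t(X * w)
          A <- XtW %*% X
          if (is.finite(determinant(A)$modulus) && rcond(A) > 1e-10) {
            ux[iy, ix] <- solve(A, XtW %*% beads$ux[sel])[1]
            uy[iy, ix] <- solve(A, XtW %*% beads$uy[sel])[1]
            done <- TRUE
          }
        }
      }
      if (!done) {
        p <- piv_lookup(piv, gxs[ix], gys[iy])
        ux[iy, ix] <- p$ux; uy[iy, ix] <- p$uy
      }
    }
  }
  out <- displacement_field(ux * ps, uy * ps, h)
  attr(out, "n_beads") <- if (is.null(beads)) 0L else length(beads$x)
  out
}

# ---- strain energy and island filters ---------------------------------------

#' Strain energy of an island region
#'
#' Computes the total strain energy `U = 1/2 * sum(T . u) h^2` over the
#' island region, the island area, the strain-energy density `U / area`, and
#' the net-force (equilibrium) ratio `|sum T| / sum |T|`. Units: with T in Pa,
#' u in µm and h in µm, `U` is in Pa µm³ = 1e-18 J; results are reported in
#' joules and, for convenience, femtojoules.
#'
#' @param u A [displacement_field()].
#' @param traction A [traction_field()] on the same grid.
#' @param island Either a logical matrix mask on the grid or an
#'   [roi_region()] polygon in grid µm coordinates (nodes with centres inside
#'   the polygon are used; the area is then the polygon area).
#' @return A one-row tibble: `U_J`, `U_fJ`, `area_um2`,
#'   `density_J_per_um2`, `density_fJ_per_um2`, `net_force_ratio`, `n_nodes`.
#' @export
strain_energy <- function(u, traction, island) {
  stopifnot(inherits(u, "displacement_field"),
            inherits(traction, "traction_field"))
  if (!identical(dim(u$ux), dim(traction$tx)) || u$h != traction$h) {
    stop("displacement and traction fields must share the grid", call. = FALSE)
  }
  h <- u$h
  if (inherits(island, "roi_region")) {
    # polygon in µm; convert to grid "pixel" coordinates (node units)
    poly_nodes <- roi_region(island$polygon / h)
    mask <- polygon_mask(dim(u$ux), poly_nodes)
    area <- polygon_area(island$polygon)
  } else {
    mask <- island
    stopifnot(is.logical(mask), identical(dim(mask), dim(u$ux)))
    area <- sum(mask) * h^2
  }
  if (!any(mask)) stop("empty island mask", call. = FALSE)
  dot <- traction$tx * u$ux + traction$ty * u$uy
  U_pa_um3 <- 0.5 * sum(dot[mask]) * h^2
  U_J <- U_pa_um3 * 1e-18
  fx <- sum(traction$tx[mask]); fy <- sum(traction$ty[mask])
  mag <- sum(sqrt(traction$tx[mask]^2 + traction$ty[mask]^2))
  nfr <- if (mag > 0) sqrt(fx^2 + fy^2) / mag else 0
  tibble::tibble(
    U_J = U_J, U_fJ = U_J * 1e15,
    area_um2 = area,
    density_J_per_um2 = U_J / area,
    density_fJ_per_um2 = U_J * 1e15 / area,
    net_force_ratio = nfr,
    n_nodes = sum(mask)
  )
}

# Shoelace polygon area (same units² as the coordinates).
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Filter islands by force equilibrium and area
#'
#' Islands whose out-of-equilibrium (net) force exceeds
#' `max_net_force_ratio` of the summed force amplitudes are discarded, as are
#' islands outside the supplied area bounds. The area bounds are study
#' configuration and must be given explicitly.
#'
#' @param islands Tibble with at least `net_force_ratio` and `area_um2`
#'   columns (one row per island, e.g. rows of [strain_energy()] results).
#' @param max_net_force_ratio Equilibrium threshold (default 0.10).
#' @param area_bounds Length-2 numeric `c(min, max)` area bounds in µm².
#' @return The input tibble with logical `kept` and character `reason`
#'   columns (`reason` is `NA` for kept islands).
#' @export
filter_islands <- function(islands, max_net_force_ratio = 0.10, area_bounds) {
  stopifnot(is.numeric(area_bounds), length(area_bounds) == 2L)
  dplyr::mutate(
    islands,
    reason = dplyr::case_when(
      .data$net_force_ratio > max_net_force_ratio ~ "out_of_equilibrium",
      .data$area_um2 < area_bounds[1] | .data$area_um2 > area_bounds[2] ~
        "area_out_of_bounds",
      TRUE ~ NA_character_
    ),
    kept = is.na(.data$reason)
  )
}

#' Express per-gel condition means as folds of the paired control
#'
#' @param per_gel Tibble with columns `gel_id`, `condition`, `mean_density`.
#' @param control_condition Name of the control condition; must be present in
#'   every gel with a positive mean.
#' @return Tibble with a `fold` column (condition mean / control mean within
#'   the same gel).
#' @export
fold_normalise <- function(per_gel, control_condition) {
  need <- c("gel_id", "condition", "mean_density")
  if (!all(need %in% names(per_gel))) {
    stop("`per_gel` must have columns gel_id, condition, mean_density",
         call. = FALSE)
  }
  out <- per_gel |>
    dplyr::group_by(.data$gel_id) |>
    dplyr::mutate(
      control_mean = .data$mean_density[match(control_condition, .data$condition)]
    ) |>
    dplyr::ungroup()
  if (any(is.na(out$control_mean))) {
    stop("control condition missing in at least one gel", call. = FALSE)
  }
  if (any(out$control_mean <= 0)) {
    stop("degenerate control mean (<= 0)", call. = FALSE)
  }
  dplyr::mutate(out, fold = .data$mean_density / .data$control_mean)
}
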