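test_that("drift registration recovers known subpixel shifts", {
  pair <- dipole_pair(seed = 11)
  img <- pair$relaxed
  expect_identical_shift <- register_drift(img, img)
  expect_equal(expect_identical_shift$dx, 0, tolerance = 1e-6)
  expect_equal(expect_identical_shift$dy, 0, tolerance = 1e-6)

  bx <- pair$truth$bead_relaxed_px
  shifted <- intensity_image(
    epimech:::render_beads(matrix(0, 400, 400), bx[, 1] + 3.25, bx[, 2] - 1.5),
    0.2)
  reg <- register_drift(shifted, img)
  expect_equal(reg$dx, 3.25, tolerance = 0.1)
  expect_equal(reg$dy, -1.5, tolerance = 0.1)

  set.seed(1)
  n1 <- intensity_image(matrix(runif(64^2), 64, 64))
  n2 <- intensity_image(matrix(runif(64^2), 64, 64))
  expect_error(register_drift(n1, n2), "registration failed")
})

test_that("displacement estimation is accurate on noise-free fixtures", {
  pair <- dipole_pair(seed = 4)
  u <- suppressWarnings(
    estimate_displacement_field(pair$stressed, pair$relaxed))
  tru <- pair$truth$displacement
  n <- min(nrow(u$ux), nrow(tru$ux)); m <- min(ncol(u$ux), ncol(tru$ux))
  rms <- sqrt(mean((u$ux[1:n, 1:m] - tru$ux[1:n, 1:m])^2 +
                     (u$uy[1:n, 1:m] - tru$uy[1:n, 1:m])^2))
  expect_lt(rms, 0.05)

  # identical images: identically zero field
  u0 <- suppressWarnings(
    estimate_displacement_field(pair$relaxed, pair$relaxed))
  expect_lt(max(abs(u0$ux)), 1e-6)

  # a rigid translation must be absorbed by registration, leaving a
  # near-zero residual field
  bx <- pair$truth$bead_relaxed_px
  moved <- intensity_image(
    epimech:::render_beads(matrix(0, 400, 400), bx[, 1] + 2.6, bx[, 2] + 1.3),
    0.2)
  reg <- register_drift(moved, pair$relaxed)
  ur <- suppressWarnings(
    estimate_displacement_field(moved, reg$relaxed_registered))
  expect_lt(sqrt(mean(ur$ux^2 + ur$uy^2)), 0.02)
})

test_that("FTTC is the exact inverse of the forward model on a shared grid", {
  sp <- tfm_dipole_spots(c(40, 40))
  tr <- epimech:::render_traction(sp, 80, 2.6)
  tf <- traction_field(tr$tx, tr$ty, 2.6, 16400, 0.5)
  u_pad <- tfm_forward(tf, pad = 2, crop = FALSE)
  rec <- fttc(u_pad, 16400, 0.5)
  n <- nrow(tf$tx)
  rel <- sqrt(mean((rec$tx[1:n, 1:n] - tf$tx)^2 +
                     (rec$ty[1:n, 1:n] - tf$ty)^2)) /
    sqrt(mean(tf$tx^2 + tf$ty^2))
  expect_lt(rel, 1e-6)
  # the padded region holds no traction
  expect_lt(max(abs(rec$tx[(n + 1):(2 * n), ])), 1e-8 * max(abs(tf$tx)))

  # zero displacement gives zero traction
  z <- fttc(displacement_field(matrix(0, 16, 16), matrix(0, 16, 16), 2.6),
            16400, 0.5)
  expect_equal(max(abs(z$tx)) + max(abs(z$ty)), 0)

  # traction is linear in E at fixed displacement
  t1 <- fttc(u_pad, 16400, 0.5)
  t2 <- fttc(u_pad, 32800, 0.5)
  expect_equal(t2$tx, 2 * t1$tx, tolerance = 1e-12)
})

test_that("strain energy is a positive quadratic form with correct units", {
  pair <- dipole_pair(seed = 2)
  u <- pair$truth$displacement
  tr <- pair$truth$traction
  z <- traction_field(tr$tx * 0, tr$ty * 0, tr$h, tr$E, tr$nu)
  expect_equal(strain_energy(u, z, pair$truth$island)$U_J, 0)

  se1 <- strain_energy(u, tr, pair$truth$island)
  u2 <- displacement_field(2 * u$ux, 2 * u$uy, u$h)
  tr2 <- traction_field(2 * tr$tx, 2 * tr$ty, tr$h, tr$E, tr$nu)
  se4 <- strain_energy(u2, tr2, pair$truth$island)
  expect_equal(se4$U_J, 4 * se1$U_J)
  expect_equal(se1$U_fJ, se1$U_J * 1e15)
  expect_equal(se1$density_J_per_um2, se1$U_J / se1$area_um2)
  expect_gt(se1$U_J, 0)

  expect_error(strain_energy(u, tr, matrix(FALSE, nrow(u$ux), ncol(u$ux))),
               "empty")
})

test_that("strain energy is invariant under rigid translation of both images", {
  pair <- dipole_pair(seed = 6)
  process <- function(stressed, relaxed) {
    reg <- register_drift(stressed, relaxed)
    u <- suppressWarnings(
      estimate_displacement_field(stressed, reg$relaxed_registered))
    tr <- fttc(u, pair$truth$E, pair$truth$nu)
    strain_energy(u, tr, pair$truth$island)$U_J
  }
  u_base <- process(pair$stressed, pair$relaxed)
  shift_img <- function(img, dx, dy) {
    px <- img$pixels
    nr <- nrow(px); nc <- ncol(px)
    out <- matrix(0, nr, nc)
    out[(dy + 1):nr, (dx + 1):nc] <- px[1:(nr - dy), 1:(nc - dx)]
    intensity_image(out, img$pixel_size)
  }
  u_shift <- process(shift_img(pair$stressed, 4, 7),
                     shift_img(pair$relaxed, 4, 7))
  expect_equal(u_shift, u_base, tolerance = 0.05)
})

test_that("the equilibrium filter keeps balanced islands and drops unbalanced ones", {
  pair <- dipole_pair(seed = 3)
  se_dipole <- strain_energy(pair$truth$displacement, pair$truth$traction,
                             pair$truth$island)
  single <- make_tfm_pair(traction_spots(40, 40, 300, 4, 0), seed = 3)
  se_single <- strain_energy(single$truth$displacement, single$truth$traction,
                             single$truth$island)
  expect_lt(se_dipole$net_force_ratio, 0.10)
  expect_gt(se_single$net_force_ratio, 0.9)
  both <- dplyr::bind_rows(se_dipole, se_single)
  both$id <- c("dipole", "single")
  out <- filter_islands(both, area_bounds = c(0, Inf))
  expect_equal(out$kept, c(TRUE, FALSE))
  expect_equal(out$reason[2], "out_of_equilibrium")

  # threshold boundary: exactly 0.10 is kept, just above is discarded
  edge <- tibble::tibble(net_force_ratio = c(0.10, 0.10 + 1e-9),
                         area_um2 = c(100, 100))
  out_edge <- filter_islands(edge, area_bounds = c(0, Inf))
  expect_equal(out_edge$kept, c(TRUE, FALSE))

  # area bounds are applied and reported
  ab <- filter_islands(tibble::tibble(net_force_ratio = 0.01,
                                      area_um2 = 50), area_bounds = c(100, 200))
  expect_false(ab$kept)
  expect_equal(ab$reason, "area_out_of_bounds")
  expect_equal(nrow(filter_islands(both[0, ], area_bounds = c(0, Inf))), 0L)
})

test_that("fold normalisation divides by the paired gel control", {
  tab <- tibble::tibble(
    gel_id = c(1, 1, 2, 2),
    condition = c("control", "kd", "control", "kd"),
    mean_density = c(2, 3, 4, 4))
  out <- fold_normalise(tab, "control")
  expect_equal(out$fold, c(1, 1.5, 1, 1))
  expect_error(fold_normalise(tab[tab$condition != "control", ], "control"),
               "control")
  tab0 <- tab; tab0$mean_density[1] <- 0
  expect_error(fold_normalise(tab0, "control"), "degenerate")
})
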