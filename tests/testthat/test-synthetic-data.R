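test_that("generators are pure functions of parameters and seed", {
  m1 <- make_monolayer(9, size = 128, seed = 5)
  m2 <- make_monolayer(9, size = 128, seed = 5)
  m3 <- make_monolayer(9, size = 128, seed = 6)
  expect_identical(m1$junction$pixels, m2$junction$pixels)
  expect_identical(m1$truth$label_map, m2$truth$label_map)
  expect_false(identical(m1$truth$label_map, m3$truth$label_map))

  f1 <- make_fret_triplet(0.3, noise_sd = 5, seed = 2)
  f2 <- make_fret_triplet(0.3, noise_sd = 5, seed = 2)
  expect_identical(f1$da$pixels, f2$da$pixels)

  s1 <- make_strand_network(3, seed = 4)
  s2 <- make_strand_network(3, seed = 4)
  expect_identical(s1$network$strands, s2$network$strands)

  p1 <- make_tfm_pair(tfm_dipole_spots(c(30, 30)), extent_um = 60, seed = 3)
  p2 <- make_tfm_pair(tfm_dipole_spots(c(30, 30)), extent_um = 60, seed = 3)
  expect_identical(p1$stressed$pixels, p2$stressed$pixels)
})

test_that("monolayer truth reflects the requested intensity levels", {
  mono <- make_monolayer(9, size = 256, J = 200, C = 100, B = 0, noise_sd = 0,
                         seed = 1)
  px <- mono$junction$pixels
  expect_equal(unique(px[mono$truth$junction_mask]), 200)
  interior <- mono$truth$dist_to_skeleton > mono$truth$junction_halfwidth + 1
  expect_equal(unique(px[interior]), 100)
  # label map partitions the image; per-cell areas account for every pixel
  expect_equal(sum(mono$truth$per_cell$area_um2),
               prod(dim(px)) * mono$truth$pixel_size^2)
  expect_error(make_monolayer(4, J = 100, C = 100, B = 0), "J > C > B")

  single <- make_monolayer(1, size = 64, seed = 1)
  inner_skel <- single$truth$junction_mask[2:63, 2:63]
  expect_false(any(inner_skel))  # only the image-boundary outline remains
  expect_equal(nrow(single$truth$edges), 0L)
})

test_that("forward elastic model is linear and scales inversely with stiffness", {
  sp <- tfm_dipole_spots(c(40, 40))
  tr <- epimech:::render_traction(sp, 80, 2.6)
  t1 <- traction_field(tr$tx, tr$ty, 2.6, 16400, 0.5)
  u1 <- tfm_forward(t1)
  # zero traction -> zero displacement
  t0 <- traction_field(tr$tx * 0, tr$ty * 0, 2.6, 16400, 0.5)
  u0 <- tfm_forward(t0)
  expect_equal(max(abs(u0$ux)) + max(abs(u0$uy)), 0)
  # doubling traction doubles displacement exactly
  t2 <- traction_field(2 * tr$tx, 2 * tr$ty, 2.6, 16400, 0.5)
  u2 <- tfm_forward(t2)
  expect_equal(u2$ux, 2 * u1$ux, tolerance = 1e-12)
  # doubling E halves displacement
  tE <- traction_field(tr$tx, tr$ty, 2.6, 32800, 0.5)
  uE <- tfm_forward(tE)
  expect_equal(uE$ux, u1$ux / 2, tolerance = 1e-12)
  expect_error(make_tfm_pair(sp, nu = 0.7), "nu")
})

test_that("forward model shows the half-space far-field radial decay", {
  # a single compact spot behaves like a point load in the far field:
  # |u| ~ 1/r, checked as u(r1)/u(r2) ~ r2/r1 on a large padded domain
  n <- 128; h <- 1
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  cx <- 33  # off-centre so the far field stays inside the domain
  tx[cx + (-2:2), cx + (-2:2)] <- 100 * outer(dnorm(-2:2), dnorm(-2:2))
  tf <- traction_field(tx, ty, h, 1000, 0.5)
  u <- tfm_forward(tf, pad = 4L)
  umag <- sqrt(u$ux^2 + u$uy^2)
  # sample along +x from the load
  r1 <- 20; r2 <- 40
  ratio <- umag[cx, cx + r1] / umag[cx, cx + r2]
  expect_equal(ratio, r2 / r1, tolerance = 0.25)
})

test_that("zero-amplitude traction yields identical bead images and zero energy", {
  spots <- traction_spots(40, 40, 0, 4, 0)
  pair <- make_tfm_pair(spots, extent_um = 60, seed = 8)
  expect_identical(pair$stressed$pixels, pair$relaxed$pixels)
  expect_equal(pair$truth$U_true_J, 0)
})

test_that("FRET triplet generator matches its declared algebra", {
  z <- make_fret_triplet(0, beta = 0, gamma = 0)
  expect_equal(max(abs(z$da$pixels)), 0)

  tri <- make_fret_triplet(0.25, beta = 0.6, gamma = 0.1)
  # algebraic inversion of the generator: Fc/(Fc + DD) = E everywhere
  fc <- tri$da$pixels - 0.6 * tri$dd$pixels - 0.1 * tri$aa$pixels
  expect_equal(fc / (fc + tri$dd$pixels),
               matrix(0.25, 64, 64), tolerance = 1e-12)
  expect_error(make_fret_triplet(1.2), "\\[0, 1\\]")
})

test_that("strand generator truth reads back from the geometry", {
  gen <- make_strand_network(4, depth_nm = 300, seed = 11)
  expect_equal(gen$truth$n_strands, 4)
  expect_equal(gen$truth$depth_nm, 300)
  expect_equal(nrow(gen$truth$breaks), 0L)
  expect_length(gen$network$strands, 4L)

  one <- make_strand_network(1, depth_nm = 300, seed = 2)
  expect_equal(one$truth$depth_nm, 0)  # one strand: no meshwork extension
  expect_error(make_strand_network(2,
    breaks = tibble::tibble(strand = 1, gap_nm = -5)), "gap")
})

test_that("adhesion fixture truth uses closed forms and flags overlap", {
  circ <- make_adhesion_image(tibble::tibble(
    x_um = 10, y_um = 10, a_um = 1, b_um = 1, angle_deg = 0, intensity = 50))
  expect_equal(circ$truth$area_um2, pi)
  expect_equal(circ$truth$max_feret_um, 2)

  ell <- make_adhesion_image(tibble::tibble(
    x_um = 10, y_um = 10, a_um = 2, b_um = 0.5, angle_deg = 30, intensity = 50))
  expect_equal(ell$truth$area_um2, pi)
  expect_equal(ell$truth$max_feret_um, 4)

  blank <- make_adhesion_image(tibble::tibble(
    x_um = numeric(), y_um = numeric(), a_um = numeric(), b_um = numeric(),
    angle_deg = numeric(), intensity = numeric()))
  expect_equal(max(blank$image$pixels), 0)
  expect_equal(nrow(blank$truth), 0L)

  pair <- make_adhesion_image(tibble::tibble(
    x_um = c(10, 11), y_um = c(10, 10), a_um = 1, b_um = 1,
    angle_deg = 0, intensity = 50))
  expect_true(all(pair$truth$overlapping))
})
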