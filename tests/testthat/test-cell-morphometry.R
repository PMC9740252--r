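test_that("cell segmentation recovers count and areas on monolayer truth", {
  mono <- make_monolayer(16, size = 512, seed = 2)
  seg <- segment_cells(mono$junction)
  truth <- mono$truth$per_cell
  expect_equal(nrow(seg$per_cell), 16L)
  # match each segmented cell to the nearest truth centroid
  match_id <- vapply(seq_len(nrow(seg$per_cell)), function(i) {
    which.min((truth$centroid_x - seg$per_cell$centroid_x[i])^2 +
                (truth$centroid_y - seg$per_cell$centroid_y[i])^2)
  }, integer(1))
  expect_equal(sort(match_id), 1:16)  # bijective matching
  interior <- !seg$per_cell$border
  expect_gte(sum(interior), 1L)
  rel <- abs(seg$per_cell$area_um2 - truth$area_um2[match_id]) /
    truth$area_um2[match_id]
  expect_true(all(rel[interior] < 0.05))
  # pixel conservation: the label map partitions the image
  expect_equal(sum(tabulate(seg$labels, nbins = 16)) + sum(seg$labels == 0),
               length(seg$labels))
})

test_that("blank junction images give an empty segmentation with a warning", {
  blank <- intensity_image(matrix(0, 64, 64))
  expect_warning(seg <- segment_cells(blank), "no junction signal")
  expect_equal(nrow(seg$per_cell), 0L)
  expect_equal(seg$status, "no_junction_signal")
})

test_that("a closed square outline yields one interior cell of known area", {
  m <- matrix(0, 160, 160)
  m[30, 30:130] <- 100; m[130, 30:130] <- 100
  m[30:130, 30] <- 100; m[30:130, 130] <- 100
  seg <- segment_cells(intensity_image(m, pixel_size = 0.1),
                       min_object_px = 10)
  inner <- dplyr::filter(seg$per_cell, !border)
  expect_equal(nrow(inner), 1L)
  expect_equal(inner$area_um2, 98^2 * 0.01, tolerance = 0.05)
})

test_that("nuclei counting splits touching blobs and ignores blanks", {
  blank <- intensity_image(matrix(0, 64, 64))
  expect_equal(as.integer(count_nuclei(blank)), 0L)

  nuc <- make_nuclei_image(n = 20, seed = 5)
  expect_equal(as.integer(count_nuclei(nuc$image)), 20L)

  # two disks overlapping by ~30% of the radius: watershed must split them
  r <- 10
  touching <- make_nuclei_image(centres = rbind(c(40, 50), c(40 + 1.7 * r, 50)),
                                radius_px = r, size = 128)
  expect_equal(as.integer(count_nuclei(touching$image)), 2L)
})

test_that("density classification follows the substrate threshold table", {
  expect_equal(as.character(classify_density(20, "glass")$call), "sparse")
  expect_equal(as.character(classify_density(45, "glass")$call), "dense")
  expect_equal(as.character(classify_density(33, "glass")$call), "intermediate")
  expect_equal(as.character(classify_density(45, "kPa40")$call), "intermediate")
  expect_equal(as.character(classify_density(20, "kPa40")$call), "sparse")
  expect_equal(as.character(classify_density(60, "kPa40")$call), "dense")
  expect_equal(as.character(classify_density(999, "kPa1")$call), "not_classified")
  # counts are scaled to the reference field area before thresholding
  half_field <- classify_density(10, "glass", field_area_um2 = 0.8e4)
  expect_equal(half_field$scaled_count, 20)
  expect_equal(as.character(half_field$call), "sparse")
  expect_error(classify_density(10, "plastic"), "substrate")
})

test_that("adhesion morphometrics match closed-form ellipse truth", {
  fix <- make_adhesion_image(tibble::tibble(
    x_um = c(5, 12, 20), y_um = c(5, 15, 8),
    a_um = c(1, 2, 1.5), b_um = c(1, 0.5, 0.8),
    angle_deg = c(0, 30, 120), intensity = 100), size = 256, pixel_size = 0.1)
  res <- adhesion_morphometrics(fix$image)
  expect_equal(nrow(res$objects), 3L)
  # match objects to truth by area ordering
  got <- dplyr::arrange(res$objects, area_um2)
  truth <- dplyr::arrange(
    tibble::tibble(area_um2 = fix$truth$area_um2,
                   max_feret_um = fix$truth$max_feret_um), area_um2,
    max_feret_um)
  ord <- order(fix$truth$area_um2, fix$truth$max_feret_um)
  # circle (area pi, F 2), ellipse a=2 b=0.5 (area pi, F 4), a=1.5 b=0.8
  expect_equal(got$area_um2, sort(fix$truth$area_um2), tolerance = 0.05)
  feret_err <- abs(sort(got$max_feret_um) - sort(fix$truth$max_feret_um))
  expect_true(all(feret_err <= 0.1))  # within one pixel (0.1 um)
  expect_equal(res$per_image$n_objects, 3L)
  expect_equal(res$per_image$mean_area_um2, mean(res$objects$area_um2))
})

test_that("caliper Feret equals the angle-sweep oracle on every object", {
  fix <- make_adhesion_image(tibble::tibble(
    x_um = c(5, 12, 20, 6), y_um = c(5, 15, 8, 20),
    a_um = c(1, 2, 1.5, 0.6), b_um = c(1, 0.5, 0.8, 0.6),
    angle_deg = c(0, 30, 120, 45), intensity = 100),
    size = 256, pixel_size = 0.1)
  res <- adhesion_morphometrics(fix$image)
  angles <- seq(0, pi, by = 0.5 * pi / 180)
  for (i in res$objects$id) {
    pts <- epimech:::object_points(res$labels, i)
    sweep_max <- max(vapply(angles, function(a) {
      proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
      diff(range(proj))
    }, numeric(1)))
    expect_equal(feret_diameter(pts), sweep_max, tolerance = 1e-4)
  }
})

test_that("measured adhesion area grows with the rendered axes", {
  areas <- vapply(c(0.8, 1.2, 1.6), function(a) {
    fix <- make_adhesion_image(tibble::tibble(
      x_um = 10, y_um = 10, a_um = a, b_um = 0.5, angle_deg = 20,
      intensity = 100), size = 200, pixel_size = 0.1)
    adhesion_morphometrics(fix$image)$objects$area_um2[1]
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("feature percentages are plain arithmetic with guarded input", {
  expect_equal(feature_percentage(0, 30), 0)
  expect_equal(feature_percentage(30, 30), 100)
  expect_equal(feature_percentage(12, 48), 25)
  expect_error(feature_percentage(1, 0), "n_cells")
  expect_error(feature_percentage(5, 3), "n_positive")
})
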