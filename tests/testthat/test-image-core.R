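test_that("containers and ROIs enforce their invariants", {
  expect_error(intensity_image(matrix(-1, 2, 2)), "non-negative")
  expect_error(intensity_image(matrix(1, 2, 2), pixel_size = 0), "positive")
  expect_error(image_stack(list()), "non-empty")
  expect_error(image_stack(list(intensity_image(matrix(1, 2, 2)),
                                intensity_image(matrix(1, 3, 3)))),
               "same shape")
  expect_error(roi_line(rbind(c(0, 0)), 1), "n >= 2")
  expect_error(roi_line(rbind(c(0, 0), c(1, 1)), 0.5), "width_px")
  expect_error(roi_region(rbind(c(0, 0), c(1, 1))), "n >= 3")
})

test_that("focus selection prefers the unblurred slice and breaks ties low", {
  cb <- checkerboard()
  stack <- image_stack(list(
    intensity_image(gblur_matrix(cb, 2)),
    intensity_image(cb),
    intensity_image(gblur_matrix(cb, 4))
  ))
  # oracle: blur strictly lowers the high-pass variance of each slice
  scores <- vapply(stack$slices,
                   function(s) var(as.vector(epimech:::laplacian_response(s$pixels))),
                   numeric(1))
  expect_identical(find_focused_slice(stack), which.max(scores))
  expect_identical(find_focused_slice(stack), 2L)

  expect_identical(find_focused_slice(image_stack(list(intensity_image(cb)))), 1L)
  twin <- image_stack(list(intensity_image(cb), intensity_image(cb)))
  expect_identical(find_focused_slice(twin), 1L)
})

test_that("extended focus projection picks the locally sharpest slice", {
  one <- image_stack(list(intensity_image(checkerboard())))
  expect_equal(extended_focus_projection(one)$pixels, checkerboard())

  set.seed(42)
  sharp <- matrix(runif(64 * 64), 64, 64)
  s1 <- sharp; s1[, 33:64] <- gblur_matrix(sharp, 3)[, 33:64]  # left sharp
  s2 <- sharp; s2[, 1:32] <- gblur_matrix(sharp, 3)[, 1:32]    # right sharp
  stack <- image_stack(list(intensity_image(s1), intensity_image(s2)))
  proj <- extended_focus_projection(stack)

  # brute-force oracle: per pixel, the slice with larger local variance of
  # the Laplacian response in a 9 px window
  lr1 <- epimech:::box_mean(epimech:::laplacian_response(s1)^2, 9L)
  lr2 <- epimech:::box_mean(epimech:::laplacian_response(s2)^2, 9L)
  oracle <- ifelse(lr1 >= lr2, s1, s2)
  expect_equal(proj$pixels, oracle)
  # away from the seam the projection equals the sharp half of each slice
  expect_equal(proj$pixels[, 5:28], sharp[, 5:28])
  expect_equal(proj$pixels[, 37:60], sharp[, 37:60])

  const <- image_stack(list(intensity_image(matrix(3, 16, 16)),
                            intensity_image(matrix(3, 16, 16))))
  expect_equal(extended_focus_projection(const)$pixels, matrix(3, 16, 16))
  # projection output stays within the input intensity range
  expect_true(all(proj$pixels >= min(s1, s2) & proj$pixels <= max(s1, s2)))
})

test_that("mean intensity along a stroke matches explicit pixel enumeration", {
  uni <- intensity_image(matrix(7, 32, 32))
  expect_equal(mean_intensity_along(uni, roi_line(rbind(c(3, 3), c(20, 25)), 5)),
               7)

  ramp <- intensity_image(matrix(rep(0:63, each = 64), 64, 64))  # value = x
  line <- roi_line(rbind(c(10, 30), c(20, 30)), width_px = 1)
  expect_equal(mean_intensity_along(ramp, line), mean(10:20))

  stripe <- matrix(0, 64, 64); stripe[31:33, ] <- 10  # rows y = 30..32
  wide <- roi_line(rbind(c(5, 31), c(60, 31)), width_px = 3)
  expect_equal(mean_intensity_along(intensity_image(stripe), wide), 10)

  outside <- roi_line(rbind(c(500, 500), c(510, 510)), 1)
  expect_error(mean_intensity_along(uni, outside), "outside")
})

test_that("stroke means are invariant under joint image/ROI translation", {
  set.seed(7)
  base <- matrix(runif(80 * 80), 80, 80)
  big <- matrix(0, 120, 120)
  for (shift in list(c(0, 0), c(13, 5), c(27, 31))) {
    img <- big
    img[shift[2] + 1:80, shift[1] + 1:80] <- base
    roi <- roi_line(rbind(c(10, 20), c(50, 44)) +
                      rep(shift, each = 2), width_px = 5)
    val <- mean_intensity_along(intensity_image(img), roi)
    if (shift[1] == 0) ref <- val else expect_equal(val, ref)
  }
})

test_that("TIFF and ROI JSON round-trip through files", {
  tmp <- tempfile(fileext = ".tif")
  px <- matrix(sample.int(65535, 32 * 16), 16, 32)
  img <- intensity_image(px, pixel_size = 0.25)
  write_image_tiff(img, tmp)                      # 16-bit
  back <- read_image_tiff(tmp, pixel_size = 0.25)
  expect_equal(back$pixels, px)
  write_image_tiff(img, tmp, bits = 32L)          # 32-bit unsigned
  expect_equal(read_image_tiff(tmp)$pixels, px)
  expect_error(write_image_tiff(img, tmp, bits = 8L), "range")

  stack <- image_stack(list(img, intensity_image(px * 0 + 7)))
  write_image_tiff(stack, tmp)
  back2 <- read_image_tiff(tmp, pixel_size = 0.25)
  expect_s3_class(back2, "image_stack")
  expect_length(back2$slices, 2L)
  expect_equal(back2$slices[[2]]$pixels, px * 0 + 7)

  tmpj <- tempfile(fileext = ".json")
  rois <- list(roi_line(rbind(c(1, 2), c(3.5, 4)), 15),
               roi_region(rbind(c(0, 0), c(10, 0), c(5, 8))))
  write_roi_json(rois, tmpj)
  back3 <- read_roi_json(tmpj)
  expect_equal(back3[[1]]$vertices, rois[[1]]$vertices)
  expect_equal(back3[[1]]$width_px, 15)
  expect_equal(back3[[2]]$polygon, rois[[2]]$polygon)
})
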