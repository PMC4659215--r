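test_that("integral intensity follows the trapezoid rule", {
  # unit integrand over a unit interval
  cube <- hyper_cube(array(1, c(2, 3, 2)), c(1000, 1001), 5)
  expect_equal(integral_intensity_image(cube), matrix(1, 2, 3))

  # all-zero cube
  cube0 <- hyper_cube(array(0, c(2, 2, 4)), c(1, 2, 3, 4), 5)
  expect_equal(integral_intensity_image(cube0), matrix(0, 2, 2))

  # hand-derived trapezoid: [0, 2, 0] over unit steps -> 2
  v <- array(0, c(1, 1, 3)); v[1, 1, ] <- c(0, 2, 0)
  cube3 <- hyper_cube(v, c(1000, 1001, 1002), 5)
  expect_equal(integral_intensity_image(cube3)[1, 1], 2.0)

  # descending wavenumber axis integrates identically
  cube_desc <- hyper_cube(v[, , 3:1, drop = FALSE], c(1002, 1001, 1000), 5)
  expect_equal(integral_intensity_image(cube_desc)[1, 1], 2.0)

  expect_error(integral_intensity_image(
    hyper_cube(array(1, c(2, 2, 1)), 1000, 5)), "single-band")
})

test_that("automatic intensity cutoff separates modes and is scale-equivariant", {
  # perfectly separated bimodal image
  img <- matrix(c(rep(0, 50), rep(10, 50)), 10, 10)
  expect_equal(background_mask_from_intensity(img, min_contrast = 1), img > 5)

  # cutoff lies strictly between the two mode groups {0,1} and {9,10}
  img4 <- matrix(rep(c(0, 1, 9, 10), each = 25), 10, 10)
  m4 <- background_mask_from_intensity(img4, min_contrast = 1)
  expect_true(all(m4[img4 >= 9]))
  expect_false(any(m4[img4 <= 1]))

  # scale equivariance: same mask under positive rescaling
  set.seed(4)
  img_r <- matrix(c(runif(40, 0, 1), runif(60, 6, 10)), 10, 10)
  expect_identical(background_mask_from_intensity(img_r),
                   background_mask_from_intensity(img_r * 37.5))

  expect_error(background_mask_from_intensity(matrix(3, 5, 5)), "degenerate")
})

test_that("an ROI with no substrate is declared all-foreground", {
  # two bright tissue populations, lower one well above half the upper
  img <- matrix(rep(c(6, 10), each = 50), 10, 10)
  expect_true(all(background_mask_from_intensity(img)))
  # true substrate at near-zero intensity is still split off
  img2 <- matrix(rep(c(0.2, 10), each = 50), 10, 10)
  expect_equal(sum(background_mask_from_intensity(img2)), 50)
})

test_that("background color estimation averages the brightest pixels", {
  v <- array(0, c(10, 10, 3))
  v[, , 1] <- 80; v[, , 2] <- 60; v[, , 3] <- 90
  # brightest 10 pixels carry the cast color
  bright <- cbind(1:10, 1:10)
  for (ch in 1:3) {
    pl <- v[, , ch]
    pl[bright] <- c(200, 190, 210)[ch]
    v[, , ch] <- pl
  }
  he <- rgb_image(v, 5)
  expect_equal(estimate_background_color(he), c(200, 190, 210))

  # a pure-white region present -> estimate ~ white
  v2 <- array(120, c(10, 10, 3)); v2[1:2, , ] <- 255
  expect_true(all(abs(estimate_background_color(rgb_image(v2, 5)) - 255) < 1e-9))
})

test_that("optical-density cast correction divides channels and snaps white", {
  v <- array(0, c(1, 3, 3))
  v[1, 1, ] <- c(200, 190, 210)      # equals bg -> pure white
  v[1, 2, ] <- c(128, 128, 128)
  v[1, 3, ] <- c(0, 50, 100)
  he <- rgb_image(v, 5)
  out <- correct_color_cast(he, c(200, 190, 210))
  expect_equal(out$values[1, 1, ], c(255, 255, 255))

  out2 <- correct_color_cast(rgb_image(v, 5), c(200, 200, 200))
  expect_equal(out2$values[1, 2, ], c(163, 163, 163))  # 255*128/200 = 163.2

  # white background is the identity away from the snap zone
  out3 <- correct_color_cast(he, c(255, 255, 255))
  expect_equal(out3$values[1, 3, ], c(0, 50, 100))

  # idempotence: re-correcting with a white background changes nothing
  out4 <- correct_color_cast(out, c(255, 255, 255))
  expect_equal(out4$values, out$values)

  expect_error(correct_color_cast(he, c(0, 200, 200)), "positive")
})

test_that("resolution matching uses exact area averaging", {
  # 100x100 at 1 um/px to 5 um/px -> 20x20
  he <- rgb_image(array(37, c(100, 100, 3)), 1)
  out <- resize_to_resolution(he, 5)
  expect_equal(dim(out$values)[1:2], c(20, 20))
  expect_equal(out$pixel_size, 5)
  # constant image stays constant
  expect_true(all(out$values == 37))

  # pixel checkerboard halved -> uniform mid-gray (each output pixel
  # averages two black and two white input pixels exactly)
  ch <- matrix(0, 8, 8)
  ch[(row(ch) + col(ch)) %% 2 == 0] <- 255
  he_ch <- rgb_image(array(rep(ch, 3), c(8, 8, 3)), 1)
  out_ch <- resize_to_resolution(he_ch, 2)
  expect_true(all(out_ch$values == 128))  # half-up round of 127.5

  # mean intensity preserved within one gray level
  set.seed(9)
  he_r <- rgb_image(array(runif(60 * 45 * 3, 0, 255), c(60, 45, 3)), 2)
  out_r <- resize_to_resolution(he_r, 7)
  expect_lt(abs(mean(out_r$values) - mean(he_r$values)), 1)

  expect_warning(resize_to_resolution(he_r, 1), "bilinear")
})

test_that("the stained-image mask is exactly the non-white pixels", {
  v <- array(255, c(4, 4, 3))
  expect_false(any(he_background_mask(rgb_image(v, 5))))
  v[2, 3, 1] <- 254
  m <- he_background_mask(rgb_image(v, 5))
  expect_equal(sum(m), 1)
  expect_true(m[2, 3])
})

test_that("phantom masks are recovered by the automatic preprocessing", {
  ph <- small_phantom(seed = 21)
  # spectral mask: classes are far brighter than substrate
  mask <- background_mask_from_intensity(
    integral_intensity_image(ph$pair$cube))
  truth <- ph$pair$roi_labels > 0
  if (any(!truth)) {
    expect_gt(mean(mask == truth), 0.98)
  } else expect_true(all(mask))
  # stained mask matches the substrate after cast correction (the rendered
  # substrate is noisy, so allow a small error rate at the border)
  he <- ph$pair$slide
  bg <- estimate_background_color(he)
  expect_true(all(abs(bg - ph$scene$cast_color *
                        ph$scene$substrate_color / 255) < 6))
  he2 <- correct_color_cast(he, bg)
  m <- he_background_mask(he2)
  expect_gt(mean(m == (ph$scene$label_map > 0)), 0.97)
})
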