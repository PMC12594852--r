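# Condensate detection, filtering and per-object measurements.

disc_image <- function(nx, cx, cy, r, value = 1) {
  px <- rep(0:(nx - 1), times = nx)
  py <- rep(0:(nx - 1), each = nx)
  matrix(value * (((px - cx)^2 + (py - cy)^2) <= r^2), nx, nx)
}

test_that("rolling-ball subtraction removes flat and smooth backgrounds, keeps small features", {
  const <- matrix(7, 64, 64)
  expect_lt(max(abs(subtract_background(const, 10))), 1e-9)

  img <- matrix(0.5, 96, 96) + disc_image(96, 48, 48, 5, 1)
  out <- subtract_background(img, 15)
  expect_gt(max(out), 0.95)  # disc peak of height 1 preserved within 5%

  grad <- outer(seq(0, 1, length.out = 96), rep(1, 96))
  res <- subtract_background(grad, 20)
  ## the opening tracks a smooth ramp up to its own radius footprint
  expect_lt(max(res[30:66, ]), 0.25)

  expect_error(subtract_background(matrix(0, 32, 32), 40), "exceeds")
})

test_that("diameter follows from area as 2 sqrt(A/pi)", {
  expect_equal(diameter_from_area(pi), 2)
  expect_equal(diameter_from_area(0.5), 0.7978846, tolerance = 1e-6)
  expect_equal(diameter_from_area(0), 0)
  expect_error(diameter_from_area(-1), "area")
})

test_that("area and circularity filters keep and reject the right objects", {
  px <- 0.05  # um per pixel
  nx <- 192
  ## disc areas 0.4 and 0.6 um^2 -> radii in pixels
  r_small <- sqrt(0.4 / pi) / px
  r_big <- sqrt(0.6 / pi) / px
  img <- disc_image(nx, 48, 48, r_small) + disc_image(nx, 130, 60, r_big)
  ## a 24 px square: circularity 4 pi / 16 ~ 0.785 < 0.8
  img[80:103, 130:153] <- 1
  det <- detect_condensates(img, detection_params(
    threshold_method = "fixed", threshold_value = 0.5, pixel_size_um = px))
  expect_equal(nrow(det), 1)
  expect_equal(det$area_um2, 0.6, tolerance = 0.05)
  expect_equal(det$diameter_um, diameter_from_area(det$area_um2))

  ## verify the square alone really fails on circularity, not area
  sq <- matrix(0, 96, 96); sq[30:53, 30:53] <- 1
  m <- sq > 0.5
  circ_sq <- 4 * pi * sum(m) / perimeter_chain(m)^2
  expect_lt(circ_sq, 0.8)
})

test_that("include_holes measures the whole droplet area of a shell", {
  px <- 0.05
  nx <- 128
  r_out <- 20; r_in <- 12
  img <- disc_image(nx, 64, 64, r_out) - disc_image(nx, 64, 64, r_in)
  p_holes <- detection_params(threshold_method = "fixed", threshold_value = 0.5,
                              pixel_size_um = px)
  det <- detect_condensates(img, p_holes)
  expect_equal(nrow(det), 1)
  expect_equal(det$area_um2, pi * r_out^2 * px^2, tolerance = 0.05)
  expect_identical(det$class, "hollow")

  p_noholes <- detection_params(threshold_method = "fixed",
                                threshold_value = 0.5, pixel_size_um = px,
                                include_holes = FALSE,
                                circularity_range = c(0.05, 1.0))
  det2 <- detect_condensates(img, p_noholes)
  expect_equal(det2$area_um2, pi * (r_out^2 - r_in^2) * px^2, tolerance = 0.05)
})

test_that("hollowness score distinguishes discs from shells and ties break homogeneous", {
  img <- disc_image(96, 48, 48, 20, 1)
  region <- img > 0.5
  h <- hollowness_score(img, region)
  expect_equal(h$score, 1, tolerance = 0.05)
  expect_identical(h$class, "homogeneous")

  shell <- disc_image(96, 48, 48, 20, 1) - disc_image(96, 48, 48, 12, 1)
  filled <- EBImage::fillHull(shell > 0.5)
  h2 <- hollowness_score(shell, filled)
  expect_lt(h2$score, 0.05)
  expect_identical(h2$class, "hollow")

  ## construct an exact score of 0.5: core intensity 1, shell intensity 2
  r_eq <- sqrt(sum(filled) / pi)
  d <- sqrt((row(filled) - 1 - 48)^2 + (col(filled) - 1 - 48)^2)
  tie <- matrix(1.5, 96, 96)
  tie[d <= 0.4 * r_eq] <- 1
  tie[d >= 0.7 * r_eq] <- 2
  h3 <- hollowness_score(tie, filled)
  expect_equal(h3$score, 0.5, tolerance = 1e-12)
  expect_identical(h3$class, "homogeneous")

  tiny <- disc_image(32, 16, 16, 2, 1)
  h4 <- hollowness_score(tiny, tiny > 0.5)
  expect_identical(h4$class, "undefined")
})

test_that("line profiles are normalised and find both shell crossings", {
  const <- matrix(4, 64, 64)
  lp <- line_profile(const, c(5, 5), c(60, 60), 50)
  expect_true(all(abs(lp$intensity - 1) < 1e-12))

  shell <- disc_image(96, 48, 48, 20, 1) - disc_image(96, 48, 48, 12, 1)
  lp2 <- line_profile(shell, c(10, 48), c(86, 48), 200)
  ## the two shell crossings appear as two separated high plateaus
  runs <- rle(lp2$intensity > 0.5)
  expect_equal(sum(runs$values), 2)
  expect_equal(max(lp2$intensity), 1)

  expect_error(line_profile(const, c(5, 5), c(5, 5)), "zero-length")
  expect_error(line_profile(const, c(-2, 5), c(10, 5)), "inside")
})

test_that("mean interior intensity is the plain mask average", {
  img <- matrix(0, 32, 32)
  img[1:16, ] <- 100
  region <- matrix(TRUE, 32, 32)
  expect_equal(mean_interior_intensity(img, region), 50)
  expect_equal(mean_interior_intensity(matrix(3.3, 8, 8) * 0 + 3.3,
                                       matrix(TRUE, 8, 8)), 3.3)
  expect_error(mean_interior_intensity(img, matrix(FALSE, 32, 32)), "empty")
})

test_that("detection is invariant under translation and 90-degree rotation", {
  px <- 0.05
  base <- disc_image(160, 50, 60, 14) + disc_image(160, 110, 100, 18)
  p <- detection_params(threshold_method = "fixed", threshold_value = 0.5,
                        pixel_size_um = px)
  d0 <- detect_condensates(base, p)
  shifted <- disc_image(160, 60, 75, 14) + disc_image(160, 120, 115, 18)
  d1 <- detect_condensates(shifted, p)
  expect_equal(sort(d0$area_um2), sort(d1$area_um2), tolerance = 1e-12)
  rot <- t(base)[, 160:1, drop = FALSE]
  d2 <- detect_condensates(rot, p)
  expect_equal(sort(d0$area_um2), sort(d2$area_um2), tolerance = 1e-12)
  expect_equal(sort(d0$circularity), sort(d2$circularity), tolerance = 1e-12)
})
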