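# Fourier enhancement, ellipse fitting and radial band profiles.

test_that("low-pass filter preserves the mean, is idempotent and linear", {
  set.seed(1)
  img <- matrix(runif(64 * 64), 64)
  f1 <- lowpass_enhance(img)
  expect_equal(mean(f1), mean(img), tolerance = 1e-12)
  expect_lt(max(abs(lowpass_enhance(f1) - f1)), 1e-12)
  const <- matrix(3.7, 32, 32)
  expect_equal(lowpass_enhance(const), const, tolerance = 1e-12)
  img2 <- matrix(runif(64 * 64), 64)
  lhs <- lowpass_enhance(2 * img - 3 * img2)
  rhs <- 2 * lowpass_enhance(img) - 3 * lowpass_enhance(img2)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("pure Nyquist checkerboard is removed entirely", {
  cb <- outer(1:64, 1:64, function(i, j) (-1)^(i + j))
  expect_lt(max(abs(lowpass_enhance(cb))), 1e-10)
  expect_error(lowpass_enhance(array(0, c(4, 4, 2))), "2D")
})

render_mask <- function(e, nx = 96, ny = 96) {
  px <- rep(0:(nx - 1), times = ny)
  py <- rep(0:(ny - 1), each = nx)
  matrix(ellipse_radius2(e, px, py) <= 1, nx, ny)
}

test_that("external-surface fit recovers rendered ellipses", {
  e <- ellipse(47.5, 42, 40, 25, 0.3)
  fit <- fit_external_ellipse(render_mask(e) * 1)
  expect_lt(abs(fit$cx - e$cx), 0.5)
  expect_lt(abs(fit$cy - e$cy), 0.5)
  expect_lt(abs(fit$a - e$a) / e$a, 0.02)
  expect_lt(abs(fit$b - e$b) / e$b, 0.02)
  expect_lt(abs(fit$theta - e$theta), 0.02)

  circ <- ellipse(47.5, 47.5, 30, 30 - 1e-9, 0)
  fitc <- fit_external_ellipse(render_mask(circ) * 1)
  expect_lt(abs(fitc$a - fitc$b) / fitc$a, 0.01)

  expect_error(fit_external_ellipse(matrix(0, 32, 32)), "no object")
})

test_that("ellipse interpolation is linear, ordered and shorter-arc in theta", {
  ann <- annulus_annotation(ellipse(50, 50, 10, 10 - 1e-9, 0),
                            ellipse(50, 50, 30, 30 - 1e-9, 0))
  mid <- interpolate_ellipses(ann, 1)[[1]]
  expect_equal(mid$a, 20, tolerance = 1e-9)
  expect_equal(c(mid$cx, mid$cy), c(50, 50))

  es <- interpolate_ellipses(ann, 20)
  areas <- vapply(es, function(e) pi * e$a * e$b, numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_length(es, 20)

  ## theta interpolation crosses the pi boundary on the shorter arc
  ann2 <- annulus_annotation(ellipse(50, 50, 12, 8, 0.1),
                             ellipse(50, 50, 30, 22, pi - 0.1))
  th <- interpolate_ellipses(ann2, 3)[[2]]$theta
  expect_true(th < 0.1 || th > pi - 0.1)

  expect_error(annulus_annotation(ellipse(50, 50, 29, 25, 0),
                                  ellipse(50, 50, 30, 26, 1)),
               "strictly inside")
})

test_that("band profile partitions the annulus exactly and is flat on uniform fields", {
  inner <- ellipse(47.5, 47.5, 20, 15, 0.2)
  outer <- ellipse(47.5, 47.5, 38, 30, 0.2)
  ann <- annulus_annotation(inner, outer)
  u <- matrix(2.5, 96, 96)
  pr <- band_profile(u, ann)
  expect_equal(nrow(pr), 21)
  expect_true(all(abs(pr$signal - 2.5) / 2.5 < 0.02))

  ## every annulus pixel lands in exactly one band
  px <- rep(0:95, times = 96); py <- rep(0:95, each = 96)
  n_annulus <- sum(ellipse_radius2(outer, px, py) <= 1 &
                     ellipse_radius2(inner, px, py) > 1)
  expect_identical(sum(pr$count), n_annulus)
})

test_that("band profile recovers a rendered linear gradient within 5% RMSE", {
  sp <- shell_image_spec(psf_sigma_px = 0, photon_scale = Inf,
                         background_level = 0, lumen_level = 0)
  r <- render_shell_image(sp)
  pr <- band_profile(r$img, r$truth$annotation)
  line <- 1 + (0.2 - 1) * pr$x
  rmse <- sqrt(mean((pr$signal - line)^2)) / mean(line)
  expect_lt(rmse, 0.05)
})

test_that("band profile is equivariant under a 90-degree rotation", {
  sp <- shell_image_spec(seed = 7)
  r <- render_shell_image(sp)
  img <- r$img
  ann <- r$truth$annotation
  pr <- band_profile(img, ann)
  ## rotate: (x, y) -> (y, nx - 1 - x)
  nx <- nrow(img)
  img_rot <- t(img)[, nx:1, drop = FALSE]
  rot_e <- function(e) ellipse(e$cy, nx - 1 - e$cx, e$a, e$b,
                               (e$theta + pi / 2) %% pi)
  ann_rot <- annulus_annotation(rot_e(ann$inner), rot_e(ann$outer))
  pr_rot <- band_profile(img_rot, ann_rot)
  expect_lt(max(abs(pr_rot$signal - pr$signal)) / mean(pr$signal), 0.01)
})

test_that("asymmetry index separates interior-peaked, symmetric and flat profiles", {
  mkprof <- function(sig) data.frame(band = seq_along(sig),
                                     x = (seq_along(sig) - 0.5) / length(sig),
                                     signal = sig, count = rep(10, length(sig)))
  flat <- asymmetry_index(mkprof(rep(1, 21)))
  expect_equal(flat$index, 0)
  expect_identical(flat$class, "symmetric")

  x <- (1:21 - 0.5) / 21
  lin <- asymmetry_index(mkprof(1 - 0.8 * x))
  ## closed form: thirds of the line 1 -> 0.2 give index = 8/9
  expect_equal(lin$index, 8 / 9, tolerance = 0.02)
  expect_identical(lin$class, "asymmetric_interior")

  dp <- asymmetry_index(mkprof(0.2 + exp(-0.5 * (x / 0.12)^2) +
                                 exp(-0.5 * ((1 - x) / 0.12)^2)))
  expect_lt(abs(dp$index), 0.01)
  expect_identical(dp$class, "symmetric")

  expect_error(asymmetry_index(mkprof(rep(1, 4))), "5 valid bands")
})

test_that("analyze_image emits one 21-band profile per annotated shell", {
  img <- matrix(0, 96, 96)
  anns <- list()
  centers <- list(c(24, 24), c(24, 68), c(68, 46))
  for (i in 1:3) {
    cc <- centers[[i]]
    sp <- shell_image_spec(outer = ellipse(cc[1], cc[2], 16, 13, 0.2),
                           inner = ellipse(cc[1], cc[2], 10, 8, 0.2),
                           psf_sigma_px = 0, photon_scale = Inf,
                           background_level = 0)
    r <- render_shell_image(sp)
    img <- img + r$img
    anns[[i]] <- r$truth$annotation
  }
  res <- analyze_image(img, anns)
  expect_equal(nrow(res$profiles), 3 * 21)
  expect_equal(nrow(res$summary), 3)
  expect_true(all(res$summary$class == "asymmetric_interior"))
})
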