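# Generators: purity given a seed, analytic truth, noise moments.

test_that("shell renders are reproducible and match the analytic truth when noise is off", {
  sp <- shell_image_spec(seed = 11)
  r1 <- render_shell_image(sp)
  r2 <- render_shell_image(sp)
  expect_identical(r1$img, r2$img)

  clean <- render_shell_image(shell_image_spec(psf_sigma_px = 0,
                                               photon_scale = Inf,
                                               background_level = 0))
  pr <- band_profile(clean$img, clean$truth$annotation)
  expect_equal(pr$signal, clean$truth$profile$signal, tolerance = 1e-9)
})

test_that("doubling the photon scale doubles the expected total signal", {
  tot <- function(ps, seed) sum(render_shell_image(
    shell_image_spec(photon_scale = ps, background_level = 0,
                     seed = seed))$img)
  t1 <- vapply(1:20, function(s) tot(100, s), numeric(1))
  t2 <- vapply(1:20, function(s) tot(200, s), numeric(1))
  ## Poisson: sd of each total ~ sqrt(expected); compare means over seeds
  ratio <- mean(t2) / mean(t1)
  se <- sqrt(1 / mean(t1) + 1 / mean(t2)) * ratio / sqrt(20)
  expect_lt(abs(ratio - 2), max(6 * se, 0.02))
})

test_that("panels respect composition, placement and ground truth", {
  sp <- panel_spec(n_objects = 1, fraction_hollow = 1, fraction_elongated = 0,
                   area_range_um2 = c(0.6, 1.0), seed = 5)
  r <- render_panel(sp)
  expect_identical(nrow(r$truth), 1L)
  expect_identical(r$truth$class, "hollow")
  det <- detect_condensates(r$img, detection_params(
    threshold_method = "fixed", threshold_value = 0.3))
  expect_identical(det$class, "hollow")

  sp2 <- panel_spec(n_objects = 60, seed = 7)
  r2 <- render_panel(sp2)
  expect_identical(nrow(r2$truth), 60L)
  ## kept set under the default filters equals the analytic subset
  det2 <- detect_condensates(r2$img, detection_params(
    threshold_method = "fixed", threshold_value = 0.3))
  kept_truth <- r2$truth[r2$truth$area_um2 >= 0.5 &
                           r2$truth$circ_analytic >= 0.8, ]
  expect_identical(nrow(det2), nrow(kept_truth))
  ## measured areas match the rasterised truth areas exactly (no noise)
  expect_equal(sort(det2$area_um2), sort(kept_truth$area_um2),
               tolerance = 1e-12)

  r3 <- render_panel(panel_spec(n_objects = 60, seed = 8))
  expect_false(identical(r3$truth$cx, r2$truth$cx))
  expect_error(render_panel(panel_spec(n_objects = 500, seed = 1)),
               "crowded")
})

test_that("field fixtures realise their formulas", {
  g <- grid_spec(32, 32)
  u <- field_fixtures("uniform", g, value = 0.5)
  expect_true(all(u$eta == 0.5))

  sm <- field_fixtures("single_mode", g, eta_bar = 0.4, k_mode = 3,
                       eps_mode = 1e-4)
  x <- (0:31)
  expect_equal(sm$eta[, 1], 0.4 + 1e-4 * cos(2 * pi * 3 * x / 32),
               tolerance = 1e-15)

  g2 <- grid_spec(64, 64)
  an <- field_fixtures("annulus", g2, r_in = 10, r_out = 20)
  expect_identical(classify_field_state(an), "hollow")

  wall <- field_fixtures("phobic_wall", g2)
  expect_true(all(wall$eta == 1))
  expect_identical(range(wall$phi), c(-1, 1))
  expect_error(field_fixtures("nope", g2), "arg")
})
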