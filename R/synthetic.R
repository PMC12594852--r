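#' Shell-image specification
#'
#' Describes a synthetic super-resolution-like image of one elliptical
#' shell-shaped condensate with a prescribed radial intensity profile,
#' Gaussian PSF blur and Poisson (photon-counting) noise.
#'
#' @param shape Image size `c(nx, ny)` in pixels.
#' @param outer,inner `ellipse` objects delimiting the shell (0-based
#'   pixel coordinates; inner strictly inside outer).
#' @param profile_family `"interior_peaked_linear"` (signal highest at
#'   the internal surface, decaying linearly outward),
#'   `"symmetric_double_peak"` (equal peaks at both surfaces) or
#'   `"flat"`.
#' @param profile_params Family-specific parameters: `inner_level` /
#'   `outer_level` for the linear family; `base`, `peak`, `peak_width`
#'   (as a fraction of the inner-to-outer distance) for the double-peak
#'   family; `level` for flat.
#' @param lumen_level Relative intensity inside the internal surface.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels (0
#'   disables blurring).
#' @param photon_scale Expected photons at unit relative intensity
#'   (`Inf` disables Poisson noise).
#' @param background_level Expected background photons per pixel.
#' @param pixel_size_nm Physical calibration (default 25 nm, a typical
#'   super-resolution pixel size).
#' @param seed RNG seed for the noise.
#' @return An object of class `shell_image_spec`.
#' @export
shell_image_spec <- function(shape = c(96, 96),
                             outer = ellipse(47.5, 47.5, 34, 27, 0.4),
                             inner = ellipse(47.5, 47.5, 24, 18, 0.4),
                             profile_family = c("interior_peaked_linear",
                                                "symmetric_double_peak",
                                                "flat"),
                             profile_params = list(),
                             lumen_level = 0.05,
                             psf_sigma_px = 1.0,
                             photon_scale = 100,
                             background_level = 2,
                             pixel_size_nm = 25,
                             seed = 1L) {
  profile_family <- match.arg(profile_family)
  defaults <- switch(profile_family,
    interior_peaked_linear = list(inner_level = 1, outer_level = 0.2),
    symmetric_double_peak = list(base = 0.25, peak = 1, peak_width = 0.2),
    flat = list(level = 1))
  profile_params <- utils::modifyList(defaults, profile_params)
  if (psf_sigma_px < 0) stop("psf_sigma_px must be >= 0")
  if (photon_scale <= 0) stop("photon_scale must be positive")
  spec <- list(shape = shape, outer = outer, inner = inner,
               profile_family = profile_family,
               profile_params = profile_params,
               lumen_level = lumen_level,
               psf_sigma_px = psf_sigma_px, photon_scale = photon_scale,
               background_level = background_level,
               pixel_size_nm = pixel_size_nm, seed = as.integer(seed))
  ## validates nesting
  annulus_annotation(inner, outer)
  class(spec) <- "shell_image_spec"
  spec
}

## Evaluate the relative radial profile at normalised distance t in [0,1].
shell_profile_value <- function(spec, t) {
  p <- spec$profile_params
  switch(spec$profile_family,
    interior_peaked_linear = p$inner_level + (p$outer_level - p$inner_level) * t,
    symmetric_double_peak = p$base + p$peak *
      (exp(-0.5 * (t / p$peak_width)^2) +
         exp(-0.5 * ((1 - t) / p$peak_width)^2)),
    flat = rep(p$level, length(t)))
}

## Normalised inner-to-outer distance of pixels, by bisection on the
## linearly interpolated ellipse family (t = 0 on the inner surface,
## t = 1 on the outer). Returns NA outside the annulus.
shell_normalized_distance <- function(spec, px, py) {
  e0 <- spec$inner; e1 <- spec$outer
  interp_inside <- function(t) {
    dth <- e1$theta - e0$theta
    if (dth > pi / 2) dth <- dth - pi
    if (dth < -pi / 2) dth <- dth + pi
    e <- list(cx = e0$cx + t * (e1$cx - e0$cx),
              cy = e0$cy + t * (e1$cy - e0$cy),
              a = e0$a + t * (e1$a - e0$a),
              b = e0$b + t * (e1$b - e0$b),
              theta = e0$theta + t * dth)
    ellipse_radius2(e, px, py) <= 1
  }
  inside_outer <- interp_inside(1)
  inside_inner <- interp_inside(0)
  lo <- rep(0, length(px)); hi <- rep(1, length(px))
  for (i in 1:22) {
    mid <- 0.5 * (lo + hi)
    ins <- interp_inside_at(e0, e1, mid, px, py)
    hi <- ifelse(ins, mid, hi)
    lo <- ifelse(ins, lo, mid)
  }
  t <- 0.5 * (lo + hi)
  t[!inside_outer] <- NA_real_
  t[inside_inner] <- NA_real_
  t
}

## Vectorised point-in-ellipse for per-point interpolation fractions.
interp_inside_at <- function(e0, e1, t, px, py) {
  dth <- e1$theta - e0$theta
  if (dth > pi / 2) dth <- dth - pi
  if (dth < -pi / 2) dth <- dth + pi
  cx <- e0$cx + t * (e1$cx - e0$cx)
  cy <- e0$cy + t * (e1$cy - e0$cy)
  a <- e0$a + t * (e1$a - e0$a)
  b <- e0$b + t * (e1$b - e0$b)
  th <- e0$theta + t * dth
  dx <- px - cx; dy <- py - cy
  u <- (dx * cos(th) + dy * sin(th)) / a
  v <- (-dx * sin(th) + dy * cos(th)) / b
  u^2 + v^2 <= 1
}

#' Render a synthetic shell image
#'
#' Paints the prescribed radial profile over the annulus between the
#' inner and outer surface, blurs with a Gaussian PSF and applies Poisson
#' noise at the given photon scale. Reproducible given the seed; the
#' returned ground truth records the analytic band-averaged profile.
#'
#' @param spec A `shell_image_spec`.
#' @param n_bands Bands used for the ground-truth band-averaged profile.
#' @return List with `img` (photon-count matrix), `truth` (list:
#'   `profile`, the analytic pre-PSF band-averaged profile;
#'   `profile_observed`, the band profile of the PSF-blurred noise-free
#'   image, i.e. the noise-free measurement reference; `family`,
#'   `annotation`, `expected_total`) and `spec`.
#' @export
render_shell_image <- function(spec, n_bands = 21) {
  stopifnot(inherits(spec, "shell_image_spec"))
  nx <- spec$shape[1]; ny <- spec$shape[2]
  px <- rep(0:(nx - 1), times = ny)
  py <- rep(0:(ny - 1), each = nx)
  t <- shell_normalized_distance(spec, px, py)
  rel <- matrix(0, nx, ny)
  inside_inner <- interp_inside_at(spec$inner, spec$outer, 0, px, py)
  rel[inside_inner] <- spec$lumen_level
  sel <- !is.na(t)
  rel[sel] <- shell_profile_value(spec, t[sel])

  ann <- annulus_annotation(spec$inner, spec$outer)
  truth_profile <- band_profile(rel, ann, n_bands = n_bands)

  if (spec$psf_sigma_px > 0)
    rel <- EBImage::gblur(rel, sigma = spec$psf_sigma_px)
  ## the noise-free measurement reference: what the band machinery
  ## reports on the PSF-blurred image before photon noise
  profile_observed <- band_profile(pmax(rel, 0), ann, n_bands = n_bands)
  if (is.finite(spec$photon_scale)) {
    expected <- spec$photon_scale * pmax(rel, 0) + spec$background_level
    img <- with_seed(spec$seed,
                     matrix(stats::rpois(length(expected), expected), nx, ny))
  } else {
    expected <- pmax(rel, 0)
    img <- expected
  }
  list(img = img,
       truth = list(profile = truth_profile,
                    profile_observed = profile_observed,
                    family = spec$profile_family,
                    annotation = ann, expected_total = sum(expected)),
       spec = spec)
}

#' Droplet-panel specification
#'
#' Describes a synthetic wide-field image containing many non-overlapping
#' condensates (filled discs and hollow annuli, plus optionally elongated
#' ellipses that fail the circularity filter) with known per-object
#' ground truth.
#'
#' @param shape Image size in pixels.
#' @param n_objects Number of objects.
#' @param fraction_hollow Fraction rendered as annuli (dark lumen).
#' @param area_range_um2 Uniform range of object areas (full droplet
#'   area, lumen included) in um^2.
#' @param fraction_elongated Fraction rendered as 3:1 ellipses
#'   (circularity ~0.66, analytically below the 0.8 filter).
#' @param pixel_size_um Calibration.
#' @param photon_scale,background_level Poisson noise model (photon scale
#'   `Inf` disables noise).
#' @param seed RNG seed.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(shape = c(640, 640), n_objects = 100,
                       fraction_hollow = 0.3, area_range_um2 = c(0.3, 1.0),
                       fraction_elongated = 0.15, pixel_size_um = 0.05,
                       photon_scale = Inf, background_level = 0,
                       seed = 1L) {
  if (n_objects < 1) stop("n_objects must be >= 1")
  if (fraction_hollow < 0 || fraction_hollow > 1)
    stop("fraction_hollow must lie in [0, 1]")
  structure(list(shape = shape, n_objects = n_objects,
                 fraction_hollow = fraction_hollow,
                 area_range_um2 = area_range_um2,
                 fraction_elongated = fraction_elongated,
                 pixel_size_um = pixel_size_um,
                 photon_scale = photon_scale,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Render a droplet panel with ground truth
#'
#' Objects are placed by rejection sampling without overlap (an error is
#' raised after 1000 consecutive failed placements). The truth table
#' records, per object, the rasterised area (pixel count of the rendered
#' mask), equivalent diameter, analytic circularity class, hollow /
#' homogeneous class and mean rendered intensity.
#'
#' @param spec A `panel_spec`.
#' @return List with `img` (intensity matrix), `truth` (data frame) and
#'   `spec`.
#' @export
render_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  nx <- spec$shape[1]; ny <- spec$shape[2]
  px_area <- spec$pixel_size_um^2
  img <- matrix(0, nx, ny)
  truth <- list()
  with_seed(spec$seed, {
    placed <- list()  # c(cx, cy, clearance radius)
    fails <- 0
    i <- 0
    while (i < spec$n_objects) {
      area <- stats::runif(1, spec$area_range_um2[1], spec$area_range_um2[2])
      hollow <- stats::runif(1) < spec$fraction_hollow
      elong <- stats::runif(1) < spec$fraction_elongated
      ratio <- if (elong) 3 else 1
      ## full-object area pi*a*b = area/px_area pixels
      bpx <- sqrt(area / px_area / (pi * ratio))
      apx <- ratio * bpx
      th <- stats::runif(1, 0, pi)
      margin <- apx + 4
      cx <- stats::runif(1, margin, nx - 1 - margin)
      cy <- stats::runif(1, margin, ny - 1 - margin)
      ok <- TRUE
      for (q in placed)
        if ((cx - q[1])^2 + (cy - q[2])^2 < (margin + q[3])^2) { ok <- FALSE; break }
      if (!ok) {
        fails <- fails + 1
        if (fails > 1000) stop("panel too crowded: 1000 failed placements")
        next
      }
      fails <- 0
      i <- i + 1
      placed[[i]] <- c(cx, cy, apx + 2)
      amp <- stats::runif(1, 0.7, 1)
      e_out <- ellipse(cx, cy, apx, bpx, th)
      x0 <- max(0, floor(cx - apx - 2)); x1 <- min(nx - 1, ceiling(cx + apx + 2))
      y0 <- max(0, floor(cy - apx - 2)); y1 <- min(ny - 1, ceiling(cy + apx + 2))
      gx <- rep(x0:x1, times = y1 - y0 + 1)
      gy <- rep(y0:y1, each = x1 - x0 + 1)
      inside <- ellipse_radius2(e_out, gx, gy) <= 1
      level <- rep(amp, sum(inside))
      if (hollow) {
        e_in <- ellipse(cx, cy, 0.55 * apx, 0.55 * bpx, th)
        lum <- ellipse_radius2(e_in, gx[inside], gy[inside]) <= 1
        level[lum] <- 0
      }
      idx <- cbind(gx[inside] + 1, gy[inside] + 1)
      img[idx] <- img[idx] + level
      npx <- sum(inside)
      truth[[i]] <- data.frame(
        id = i, cx = cx, cy = cy, area_px = npx,
        area_um2 = npx * px_area,
        diameter_um = diameter_from_area(npx * px_area),
        shape = if (elong) "elongated" else "round",
        circ_analytic = ellipse_circularity(apx, bpx),
        class = if (hollow) "hollow" else "homogeneous",
        amplitude = amp,
        mean_intensity = mean(level))
    }
    if (is.finite(spec$photon_scale)) {
      lambda <- spec$photon_scale * img + spec$background_level
      img <- matrix(stats::rpois(length(lambda), lambda), nx, ny)
    } else if (spec$background_level > 0) {
      img <- img + spec$background_level
    }
  })
  list(img = img, truth = do.call(rbind, truth), spec = spec)
}

## Analytic circularity of an ellipse (Ramanujan perimeter).
ellipse_circularity <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  per <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  4 * pi * (pi * a * b) / per^2
}
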