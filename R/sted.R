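#' Fourier low-pass enhancement of a microscopy image
#'
#' Transforms the image to frequency space, zeroes all radial frequency
#' components above `cutoff_fraction` of the Nyquist frequency and
#' transforms back, suppressing high-frequency (shot) noise before
#' annotation. The DC component is never touched, so the mean intensity
#' is preserved exactly; the filter is a projection (applying it twice
#' equals applying it once) and is linear.
#'
#' @param img Numeric matrix (indexed `[x + 1, y + 1]`).
#' @param cutoff_fraction Fraction of the Nyquist frequency retained,
#'   in (0, 1]. The default 0.5 corresponds to a cutoff at half the
#'   frequency-grid length.
#' @return Filtered image matrix of the same dimension.
#' @export
lowpass_enhance <- function(img, cutoff_fraction = 0.5) {
  if (!is.matrix(img)) stop("img must be a 2D matrix")
  if (!is.numeric(cutoff_fraction) || cutoff_fraction <= 0 || cutoff_fraction > 1)
    stop("cutoff_fraction must lie in (0, 1]")
  nx <- nrow(img); ny <- ncol(img)
  fx <- fft_freq(nx)
  fy <- fft_freq(ny)
  fr <- sqrt(outer(fx^2, rep(1, ny)) + outer(rep(1, nx), fy^2))
  keep <- fr <= cutoff_fraction * 0.5 + 1e-12
  Re(stats::fft(stats::fft(img) * keep, inverse = TRUE)) / (nx * ny)
}

## Discrete Fourier frequencies in cycles per pixel.
fft_freq <- function(n) {
  half <- floor(n / 2)
  c(0:half, if (n > 1) (-(ceiling(n / 2) - 1)):(-1)) / n
}

#' Automatic calibration of the external surface
#'
#' Estimates the outer surface of the dominant bright object as the
#' second-moment ellipse of its Otsu-thresholded mask (largest connected
#' component).
#'
#' @param img Numeric matrix.
#' @return An `ellipse` (0-based pixel coordinates).
#' @export
fit_external_ellipse <- function(img) {
  if (!is.matrix(img)) stop("img must be a 2D matrix")
  rng <- range(img)
  if (rng[2] <= rng[1]) stop("no object detected: image is constant")
  norm <- (img - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  if (!any(mask)) stop("no object detected: empty mask after thresholding")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  mask_ellipse(lab == which.max(sizes))
}

## Second-moment ellipse of a logical mask (filled-region convention:
## semi-axis = 2 * sqrt(eigenvalue of the coordinate covariance)).
mask_ellipse <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("no object detected: empty mask")
  x <- idx[, 1] - 1; y <- idx[, 2] - 1
  cx <- mean(x); cy <- mean(y)
  n <- length(x)
  ## second moments of the pixel set plus the 1/12 single-pixel term
  sxx <- sum((x - cx)^2) / n + 1 / 12
  syy <- sum((y - cy)^2) / n + 1 / 12
  sxy <- sum((x - cx) * (y - cy)) / n
  cov <- matrix(c(sxx, sxy, sxy, syy), 2, 2)
  eg <- eigen(cov, symmetric = TRUE)
  a <- 2 * sqrt(eg$values[1])
  b <- 2 * sqrt(max(eg$values[2], 1e-12))
  theta <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  ellipse(cx, cy, a, b, theta)
}

#' Area-normalised radial band profile of an annotated shell
#'
#' Implements the segmented-region measurement: `n_bands - 1`
#' intermediate ellipses are interpolated between the annotated internal
#' and external surfaces, every pixel between the surfaces is assigned to
#' the band between consecutive ellipses containing it (inner boundary
#' excluded, outer included), and each band reports its area-normalised
#' signal against the normalised distance from the internal surface.
#'
#' @param img Numeric matrix.
#' @param ann An `annulus_annotation`.
#' @param n_bands Number of bands (default 21: twenty interpolated
#'   ellipses plus the two annotated surfaces).
#' @param normalization `"mean"` (default): band signal is the mean pixel
#'   intensity (sum / pixel count); `"total_fraction"`: band sum divided
#'   by the total signal in the annulus.
#' @return A `radial_profile` data frame with columns `band`, `x`
#'   (band-midpoint normalised distance from the internal surface),
#'   `signal` and `count`. Empty bands report `count = 0` and `NA`
#'   signal.
#' @export
band_profile <- function(img, ann, n_bands = 21,
                         normalization = c("mean", "total_fraction")) {
  if (!is.matrix(img)) stop("img must be a 2D matrix")
  stopifnot(inherits(ann, "annulus_annotation"))
  normalization <- match.arg(normalization)
  if (n_bands < 2) stop("n_bands must be >= 2")
  nx <- nrow(img); ny <- ncol(img)
  bd <- ellipse_boundary(ann$outer, 180)
  if (min(bd$x) < -0.5 || max(bd$x) > nx - 0.5 ||
      min(bd$y) < -0.5 || max(bd$y) > ny - 0.5)
    stop("annulus extends outside the image")

  boundaries <- c(list(ann$inner), interpolate_ellipses(ann, n_bands - 1),
                  list(ann$outer))
  x0 <- max(0, floor(ann$outer$cx - ann$outer$a - 2))
  x1 <- min(nx - 1, ceiling(ann$outer$cx + ann$outer$a + 2))
  y0 <- max(0, floor(ann$outer$cy - ann$outer$a - 2))
  y1 <- min(ny - 1, ceiling(ann$outer$cy + ann$outer$a + 2))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  ## number of boundaries each pixel is inside (boundary itself counts
  ## as inside, giving inner-exclusive / outer-inclusive half-open bands)
  cnt <- integer(length(px))
  for (e in boundaries)
    cnt <- cnt + (ellipse_radius2(e, px, py) <= 1)
  band <- (n_bands + 1L) - cnt  # 1..n_bands between the surfaces
  sel <- cnt >= 1L & cnt <= n_bands
  vals <- img[cbind(px + 1L, py + 1L)]
  counts <- tabulate(band[sel], nbins = n_bands)
  sums <- vapply(seq_len(n_bands), function(b)
    sum(vals[sel][band[sel] == b]), numeric(1))
  signal <- switch(normalization,
    mean = ifelse(counts > 0, sums / counts, NA_real_),
    total_fraction = ifelse(counts > 0, sums / sum(sums), NA_real_))
  out <- data.frame(band = seq_len(n_bands),
                    x = (seq_len(n_bands) - 0.5) / n_bands,
                    signal = signal, count = counts)
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Asymmetry index of a radial profile
#'
#' Quantifies the visual contrast between interior-enriched shells
#' (signal highest at the internal surface, decaying outward) and
#' symmetric, vesicle-like shells (equal signal at both surfaces):
#' `index = (mean(inner third) - mean(outer third)) / mean(all)`.
#' The profile is classified `asymmetric_interior` when `index >= 0.2`
#' and the profile trends monotonically downward (Spearman correlation
#' of signal against distance <= -0.7), `symmetric` when
#' `|index| < 0.1`, and `other` otherwise.
#'
#' @param profile A `radial_profile` (or data frame with `x`, `signal`,
#'   `count`).
#' @return A list with `index`, `spearman` and `class`.
#' @export
asymmetry_index <- function(profile) {
  ok <- is.finite(profile$signal) & profile$count > 0
  if (sum(ok) < 5) stop("asymmetry_index requires at least 5 valid bands")
  x <- profile$x[ok]
  s <- profile$signal[ok]
  n <- length(s)
  third <- max(1, floor(n / 3))
  idx <- (mean(s[seq_len(third)]) - mean(s[seq.int(n - third + 1, n)])) / mean(s)
  rho <- if (stats::sd(s) == 0) 0 else
    suppressWarnings(stats::cor(x, s, method = "spearman"))
  cls <- if (idx >= 0.2 && rho <= -0.7) "asymmetric_interior"
         else if (abs(idx) < 0.1) "symmetric"
         else "other"
  list(index = idx, spearman = rho, class = cls)
}

#' Radial-profile analysis of an annotated image
#'
#' Applies the Fourier low-pass enhancement, measures a band profile per
#' annotated shell and classifies each profile's asymmetry.
#'
#' @param img Numeric matrix.
#' @param annotations List of `annulus_annotation` (or a path to an
#'   annotation JSON readable by [read_annotations()]).
#' @param n_bands Number of bands per shell.
#' @param cutoff_fraction Low-pass cutoff (see [lowpass_enhance()]);
#'   `NULL` skips the enhancement.
#' @param normalization Band normalisation (see [band_profile()]).
#' @param image_id Identifier copied into the output tables.
#' @return List with `profiles` (one row per condensate and band) and
#'   `summary` (one row per condensate: asymmetry index, Spearman
#'   correlation and class).
#' @export
analyze_image <- function(img, annotations, n_bands = 21,
                          cutoff_fraction = 0.5,
                          normalization = "mean", image_id = "image") {
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (inherits(annotations, "annulus_annotation"))
    annotations <- list(annotations)
  if (!length(annotations)) stop("no annotations supplied")
  enh <- if (is.null(cutoff_fraction)) img else
    lowpass_enhance(img, cutoff_fraction)
  profiles <- list()
  summaries <- list()
  for (i in seq_along(annotations)) {
    pr <- band_profile(enh, annotations[[i]], n_bands = n_bands,
                       normalization = normalization)
    asym <- asymmetry_index(pr)
    profiles[[i]] <- cbind(image = image_id, condensate = i, pr)
    summaries[[i]] <- data.frame(image = image_id, condensate = i,
                                 index = asym$index,
                                 spearman = asym$spearman,
                                 class = asym$class)
  }
  list(profiles = do.call(rbind, profiles),
       summary = do.call(rbind, summaries))
}

#' Suggest an internal surface from the external one
#'
#' Convenience extension (the reference procedure annotates internal
#' surfaces manually): walks inward along rays from the shell center,
#' locates the intensity valley inside the shell on each ray and returns
#' the external ellipse shrunk to the median valley fraction.
#'
#' @param img Numeric matrix (ideally already low-pass enhanced).
#' @param outer External `ellipse`.
#' @param n_rays Number of rays.
#' @param search Fractions of the external surface searched for the
#'   valley.
#' @return An `ellipse` estimate of the internal surface.
#' @export
suggest_inner_ellipse <- function(img, outer, n_rays = 90,
                                  search = c(0.15, 0.9)) {
  t <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  fr <- seq(search[1], search[2], length.out = 40)
  ct <- cos(outer$theta); st <- sin(outer$theta)
  valley <- vapply(t, function(th) {
    px <- outer$a * cos(th); py <- outer$b * sin(th)
    xs <- outer$cx + fr * (px * ct - py * st)
    ys <- outer$cy + fr * (px * st + py * ct)
    ix <- pmin(pmax(round(xs), 0), nrow(img) - 1)
    iy <- pmin(pmax(round(ys), 0), ncol(img) - 1)
    v <- img[cbind(ix + 1, iy + 1)]
    fr[which.min(v)]
  }, numeric(1))
  f <- stats::median(valley)
  ellipse(outer$cx, outer$cy, outer$a * f, outer$b * f, outer$theta)
}
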