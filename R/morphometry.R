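#' Detection parameters for condensate morphometry
#'
#' Mirrors the reference particle-analysis workflow: rolling-ball
#' background subtraction (radius 50 px), auto threshold, minimum
#' particle size 0.5 um^2, circularity range 0.8--1.0 and hole filling
#' for shell-like images so the whole droplet area is measured.
#'
#' @param background_radius_px Rolling-ball radius in pixels.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_value Absolute threshold for `"fixed"`.
#' @param min_area_um2 Minimum particle area in um^2.
#' @param circularity_range Kept circularity interval `[low, high]`;
#'   `high = 1.0` accepts up to 1.05 to absorb discretisation bias.
#' @param include_holes Fill enclosed holes before measuring (so a shell
#'   reports the whole droplet area).
#' @param pixel_size_um Pixel calibration in um per pixel.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(background_radius_px = 50,
                             threshold_method = c("otsu", "fixed"),
                             threshold_value = NULL,
                             min_area_um2 = 0.5,
                             circularity_range = c(0.8, 1.0),
                             include_holes = TRUE,
                             pixel_size_um = 0.05) {
  threshold_method <- match.arg(threshold_method)
  lo <- circularity_range[1]; hi <- circularity_range[2]
  if (!(lo > 0 && lo <= hi && hi <= 1.0))
    stop("circularity_range must satisfy 0 < low <= high <= 1.0")
  if (min_area_um2 <= 0) stop("min_area_um2 must be positive")
  if (!is.null(pixel_size_um) && pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  if (threshold_method == "fixed" && is.null(threshold_value))
    stop("threshold_value required for fixed thresholding")
  structure(list(background_radius_px = background_radius_px,
                 threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_area_um2 = min_area_um2,
                 circularity_range = circularity_range,
                 include_holes = include_holes,
                 pixel_size_um = pixel_size_um),
            class = "detection_params")
}

#' Rolling-ball background subtraction
#'
#' Removes the smooth background estimated by a grayscale morphological
#' opening with a disc structuring element of the given radius; the
#' result is clipped at zero. Features smaller than the ball survive
#' because the ball cannot fit inside them.
#'
#' @param img Numeric matrix.
#' @param radius_px Ball radius in pixels (>= 1, smaller than the image).
#' @return Background-corrected image.
#' @export
subtract_background <- function(img, radius_px = 50) {
  if (!is.matrix(img)) stop("img must be a 2D matrix")
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (2 * radius_px + 1 > min(dim(img)))
    stop("background radius exceeds the image size")
  r <- as.integer(radius_px)
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  ## replicate-pad so the opening sees no artificial zero border, and
  ## rescale to [0, 1] (the morphology backend clamps intensities)
  ix <- c(rep(1, r), seq_len(nrow(img)), rep(nrow(img), r))
  iy <- c(rep(1, r), seq_len(ncol(img)), rep(ncol(img), r))
  padded <- img[ix, iy]
  lo <- min(padded); hi <- max(padded)
  if (hi > lo) {
    scaled <- (padded - lo) / (hi - lo)
    bg <- lo + (hi - lo) *
      EBImage::opening(scaled, brush)[r + seq_len(nrow(img)),
                                      r + seq_len(ncol(img))]
  } else {
    bg <- matrix(lo, nrow(img), ncol(img))
  }
  pmax(img - bg, 0)
}

#' Chain-code perimeter of a labelled object
#'
#' Perimeter measured along the ordered 8-connected boundary contour
#' (axis steps count 1, diagonal steps sqrt(2)) plus a half-pixel
#' boundary-offset correction of 4: the contour connects pixel centers,
#' while the region boundary runs half a pixel outside it, which for a
#' convex object adds between pi (smooth) and 4 (right-angled). With
#' this convention an axis-aligned square measures its exact perimeter
#' (circularity 4*pi/16 ~ 0.785) and digital discs measure circularity
#' 0.85-1.0.
#'
#' @param mask Logical matrix containing a single object.
#' @return Perimeter in pixels.
#' @export
perimeter_chain <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) stop("mask contains no object")
  ct <- oc[[1]]
  if (nrow(ct) < 2) return(4)  # single pixel
  d <- sqrt(rowSums((ct - ct[c(2:nrow(ct), 1), ])^2))
  sum(d) + 4
}

#' Detect and measure condensates
#'
#' Threshold, label connected components, optionally fill enclosed holes,
#' filter by area and circularity (`4 pi A / P^2`), exclude objects
#' touching the image border, and measure each kept region: area,
#' diameter from area, circularity, mean intensity and hollowness.
#' Regions are returned sorted by area, largest first.
#'
#' @param img Numeric matrix of intensities (already background
#'   corrected; see [subtract_background()]).
#' @param p A `detection_params`.
#' @return A data frame, one row per kept condensate: `id`, `cx`, `cy`
#'   (0-based centroid), `area_um2`, `diameter_um`, `circularity`,
#'   `mean_intensity`, `hollowness`, `class`. The labelled mask matrix is
#'   attached as attribute `"labels"` (label values match `id`).
#' @export
detect_condensates <- function(img, p = detection_params()) {
  if (!is.matrix(img)) stop("img must be a 2D matrix")
  if (is.null(p$pixel_size_um))
    stop("pixel calibration required for area-based filtering")
  px2 <- p$pixel_size_um^2
  rng <- range(img)
  thr <- if (p$threshold_method == "otsu") {
    if (rng[2] <= rng[1]) Inf else {
      norm <- (img - rng[1]) / (rng[2] - rng[1])
      rng[1] + (rng[2] - rng[1]) *
        EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    }
  } else p$threshold_value
  mask <- img > thr
  empty <- data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
                      area_um2 = numeric(0), diameter_um = numeric(0),
                      circularity = numeric(0), mean_intensity = numeric(0),
                      hollowness = numeric(0), class = character(0))
  if (!any(mask)) {
    attr(empty, "labels") <- matrix(0L, nrow(img), ncol(img))
    return(empty)
  }
  lab <- EBImage::bwlabel(mask)
  if (p$include_holes) lab <- EBImage::fillHull(lab)
  nlab <- max(lab)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  rows <- list()
  keep_labels <- integer(0)
  for (l in seq_len(nlab)) {
    m <- lab == l
    npx <- sum(m)
    if (npx == 0 || l %in% border) next
    area <- npx * px2
    if (area < p$min_area_um2) next
    per <- perimeter_chain(m)
    circ <- 4 * pi * npx / per^2
    if (circ < p$circularity_range[1] ||
        circ > p$circularity_range[2] + 0.05) next
    idx <- which(m, arr.ind = TRUE)
    cx <- mean(idx[, 1]) - 1; cy <- mean(idx[, 2]) - 1
    h <- hollowness_score(img, m)
    rows[[length(rows) + 1]] <- data.frame(
      id = l, cx = cx, cy = cy, area_um2 = area,
      diameter_um = diameter_from_area(area),
      circularity = circ, mean_intensity = mean(img[m]),
      hollowness = h$score,
      class = h$class)
    keep_labels <- c(keep_labels, l)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out)) out <- out[order(-out$area_um2), , drop = FALSE]
  lab_mat <- matrix(as.integer(lab), nrow(img), ncol(img))
  lab_mat[!(lab_mat %in% keep_labels)] <- 0L
  attr(out, "labels") <- lab_mat
  out
}

#' Diameter of a circle of equal area
#'
#' @param area_um2 Area (um^2), vectorised.
#' @return `2 * sqrt(area / pi)`.
#' @examples
#' diameter_from_area(pi) # 2
#' @export
diameter_from_area <- function(area_um2) {
  if (any(!is.finite(area_um2)) || any(area_um2 < 0))
    stop("area must be finite and >= 0")
  2 * sqrt(area_um2 / pi)
}

#' Hollowness score of a detected region
#'
#' Ratio of the mean intensity in the region core (disc of
#' `core_fraction` times the equivalent radius around the centroid) to
#' the mean intensity in the shell band (outer 30 percent of the
#' equivalent radius, restricted to the region mask). A dark lumen gives
#' a score near 0; a uniform droplet gives a score near 1. Classified
#' `hollow` when `score < cutoff` (strict; a score equal to the cutoff is
#' `homogeneous`).
#'
#' @param img Numeric matrix.
#' @param region Logical mask of the (hole-filled) region.
#' @param core_fraction Core radius as a fraction of the equivalent
#'   radius.
#' @param cutoff Classification cutoff.
#' @return List with `score` and `class` (`NA` and `"undefined"` when the
#'   core holds fewer than 9 pixels).
#' @export
hollowness_score <- function(img, region, core_fraction = 0.4, cutoff = 0.5) {
  idx <- which(region, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty region")
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  r_eq <- sqrt(sum(region) / pi)
  d <- sqrt((idx[, 1] - cx)^2 + (idx[, 2] - cy)^2)
  core <- d <= core_fraction * r_eq
  shell <- d >= 0.7 * r_eq
  if (sum(core) < 9)
    return(list(score = NA_real_, class = "undefined"))
  vals <- img[region]
  ms <- mean(vals[shell])
  score <- if (ms <= 0) NA_real_ else mean(vals[core]) / ms
  cls <- if (!is.finite(score)) "undefined"
         else if (score < cutoff) "hollow" else "homogeneous"
  list(score = score, class = cls)
}

#' Normalised line profile
#'
#' Bilinear intensity samples along a segment, normalised so the maximum
#' equals 1.
#'
#' @param img Numeric matrix.
#' @param p0,p1 Endpoints `c(x, y)` in 0-based pixel coordinates, inside
#'   the image.
#' @param n_samples Number of samples.
#' @return Data frame with `t` (position along the segment, 0 to 1) and
#'   `intensity`.
#' @export
line_profile <- function(img, p0, p1, n_samples = 100) {
  if (all(p0 == p1)) stop("zero-length segment")
  for (pt in list(p0, p1))
    if (pt[1] < 0 || pt[1] > nrow(img) - 1 || pt[2] < 0 || pt[2] > ncol(img) - 1)
      stop("endpoints must lie inside the image")
  t <- seq(0, 1, length.out = n_samples)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  x0 <- pmin(floor(xs), nrow(img) - 2); fx <- xs - x0
  y0 <- pmin(floor(ys), ncol(img) - 2); fy <- ys - y0
  v <- img[cbind(x0 + 1, y0 + 1)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 2, y0 + 1)] * fx * (1 - fy) +
    img[cbind(x0 + 1, y0 + 2)] * (1 - fx) * fy +
    img[cbind(x0 + 2, y0 + 2)] * fx * fy
  mx <- max(v)
  data.frame(t = t, intensity = if (mx > 0) v / mx else v)
}

#' Mean intensity inside a region
#'
#' @param img Numeric matrix.
#' @param region Logical mask (hole-filled region of a condensate).
#' @return Arithmetic mean of the pixel intensities over the mask.
#' @export
mean_interior_intensity <- function(img, region) {
  if (!any(region)) stop("empty region")
  mean(img[region])
}

#' Welch two-sample t statistic
#'
#' Convenience wrapper for comparing per-object measurements between two
#' groups (unpaired, unequal variances).
#'
#' @param x,y Numeric vectors.
#' @return The `htest` object from [stats::t.test()].
#' @export
welch_t <- function(x, y) stats::t.test(x, y, var.equal = FALSE)
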