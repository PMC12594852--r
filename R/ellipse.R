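#' Ellipse in pixel coordinates
#'
#' Pixel coordinates are 0-based with pixel centers at integers; image
#' matrices are indexed `img[x + 1, y + 1]`.
#'
#' @param cx,cy Center.
#' @param a,b Semi-axes in pixels, `a >= b > 0`.
#' @param theta Rotation of the major axis in radians, normalised to
#'   `[0, pi)`.
#' @return An object of class `ellipse`.
#' @export
ellipse <- function(cx, cy, a, b, theta = 0) {
  if (!all(is.finite(c(cx, cy, a, b, theta)))) stop("ellipse parameters must be finite")
  if (b <= 0 || a < b) stop("ellipse requires a >= b > 0")
  theta <- theta %% pi
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta),
            class = "ellipse")
}

#' @export
print.ellipse <- function(x, ...) {
  cat(sprintf("<ellipse> center (%.2f, %.2f), semi-axes (%.2f, %.2f), theta %.3f rad\n",
              x$cx, x$cy, x$a, x$b, x$theta))
  invisible(x)
}

#' Test points against an ellipse
#'
#' @param e An `ellipse`.
#' @param x,y Point coordinates (0-based pixel units).
#' @return Numeric vector: squared normalised elliptic radius (<= 1 is
#'   inside or on the boundary).
#' @export
ellipse_radius2 <- function(e, x, y) {
  dx <- x - e$cx
  dy <- y - e$cy
  ct <- cos(e$theta); st <- sin(e$theta)
  u <- (dx * ct + dy * st) / e$a
  v <- (-dx * st + dy * ct) / e$b
  u^2 + v^2
}

ellipse_area <- function(e) pi * e$a * e$b

## Sample n points on the ellipse boundary.
ellipse_boundary <- function(e, n = 360) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ct <- cos(e$theta); st <- sin(e$theta)
  px <- e$a * cos(t); py <- e$b * sin(t)
  list(x = e$cx + px * ct - py * st, y = e$cy + px * st + py * ct)
}

#' Annulus annotation: inner and outer surface ellipses
#'
#' The inner boundary must lie strictly inside the outer boundary
#' (verified by sampling 360 boundary points).
#'
#' @param inner,outer `ellipse` objects delimiting the condensate shell.
#' @return An object of class `annulus_annotation`.
#' @export
annulus_annotation <- function(inner, outer) {
  stopifnot(inherits(inner, "ellipse"), inherits(outer, "ellipse"))
  bd <- ellipse_boundary(inner, 360)
  if (any(ellipse_radius2(outer, bd$x, bd$y) >= 1))
    stop("inner ellipse must lie strictly inside the outer ellipse")
  structure(list(inner = inner, outer = outer), class = "annulus_annotation")
}

#' @export
print.annulus_annotation <- function(x, ...) {
  cat("<annulus_annotation>\n  inner: ")
  print(x$inner)
  cat("  outer: ")
  print(x$outer)
  invisible(x)
}

#' Linearly interpolate ellipses between the annotated surfaces
#'
#' Generates `n_intermediate` ellipses whose parameters
#' `(cx, cy, a, b, theta)` are linearly interpolated between the inner
#' and outer surface at fractions `k / (n_intermediate + 1)`; `theta` is
#' interpolated along the shorter angular arc (ellipse orientation has
#' period pi). Together with the two boundaries the result delimits
#' `n_intermediate + 1` annular bands.
#'
#' @param ann An `annulus_annotation`.
#' @param n_intermediate Number of intermediate ellipses (default 20).
#' @return List of `ellipse` objects, ordered inner to outer.
#' @export
interpolate_ellipses <- function(ann, n_intermediate = 20) {
  stopifnot(inherits(ann, "annulus_annotation"))
  if (n_intermediate < 1) stop("n_intermediate must be >= 1")
  e0 <- ann$inner; e1 <- ann$outer
  dth <- e1$theta - e0$theta
  if (dth > pi / 2) dth <- dth - pi
  if (dth < -pi / 2) dth <- dth + pi
  lapply(seq_len(n_intermediate), function(k) {
    f <- k / (n_intermediate + 1)
    ellipse(cx = e0$cx + f * (e1$cx - e0$cx),
            cy = e0$cy + f * (e1$cy - e0$cy),
            a = e0$a + f * (e1$a - e0$a),
            b = e0$b + f * (e1$b - e0$b),
            theta = (e0$theta + f * dth) %% pi)
  })
}
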