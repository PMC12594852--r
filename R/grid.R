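#' Simulation grid specification
#'
#' Defines the periodic rectangular grid on which all order-parameter
#' fields live. Cells are cell-centered with the origin at the grid
#' corner; all geometry is expressed in grid units (`dx`).
#'
#' Spectral wavenumbers for the pseudo-spectral operators are precomputed
#' and cached in the returned object.
#'
#' @param nx,ny Number of cells in x and y. Must be powers of two and at
#'   least 16 (the solver relies on FFTs).
#' @param dx Cell size (dimensionless). Must be positive.
#' @param periodic Logical; only periodic boundaries are supported.
#' @return An object of class `grid_spec` with fields `nx`, `ny`, `dx`,
#'   `periodic` and cached wavenumber arrays `kx`, `ky`, `k2` (=|k|^2)
#'   and `k4`.
#' @examples
#' g <- grid_spec(64, 64)
#' g$nx
#' @export
grid_spec <- function(nx, ny = nx, dx = 1, periodic = TRUE) {
  is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
  if (nx < 16 || ny < 16 || !is_pow2(nx) || !is_pow2(ny))
    stop("nx and ny must be powers of two and >= 16")
  if (!is.numeric(dx) || dx <= 0) stop("dx must be positive")
  if (!isTRUE(periodic)) stop("only periodic grids are supported")
  kx1 <- 2 * pi / (nx * dx) * c(0:(nx / 2), (-nx / 2 + 1):(-1))
  ky1 <- 2 * pi / (ny * dx) * c(0:(ny / 2), (-ny / 2 + 1):(-1))
  kx <- matrix(kx1, nx, ny)
  ky <- matrix(ky1, nx, ny, byrow = TRUE)
  k2 <- kx^2 + ky^2
  g <- list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
            periodic = TRUE, kx = kx, ky = ky, k2 = k2, k4 = k2^2)
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d periodic grid, dx = %g\n", x$nx, x$ny, x$dx))
  invisible(x)
}

## Forward/inverse FFT helpers (unnormalised forward, normalised inverse).
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)
ifft2_re <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

## Domain area in grid units.
grid_area <- function(grid) grid$nx * grid$ny * grid$dx^2

## Matrix of distances from a point (cx, cy) in grid units, cell-centered
## coordinates x = (i - 1) * dx. Periodic minimum-image convention.
grid_radius <- function(grid, cx, cy) {
  x <- ((seq_len(grid$nx) - 1) * grid$dx)
  y <- ((seq_len(grid$ny) - 1) * grid$dx)
  lx <- grid$nx * grid$dx
  ly <- grid$ny * grid$dx
  dxv <- abs(x - cx); dxv <- pmin(dxv, lx - dxv)
  dyv <- abs(y - cy); dyv <- pmin(dyv, ly - dyv)
  sqrt(outer(dxv^2, rep(1, grid$ny)) + outer(rep(1, grid$nx), dyv^2))
}
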