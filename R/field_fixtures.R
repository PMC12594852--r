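#' Canonical solver test fields
#'
#' Renders named analytic field configurations used by the solver's
#' verification oracles (dispersion relation, flood-fill classification,
#' hydrophobic gating).
#'
#' @param kind One of `"uniform"` (constant `eta`), `"single_mode"`
#'   (`eta_bar + eps * cos(k x)`), `"disc"` (sharp tanh disc),
#'   `"annulus"` (tanh ring) or `"phobic_wall"` (uniform dense `eta` with
#'   a hydrophilic `phi > 0` stripe wall and `chi` loaded on one side).
#' @param grid A `grid_spec`.
#' @param value Constant level for `"uniform"`.
#' @param eta_bar,k_mode,eps_mode Parameters of `"single_mode"`; `k_mode`
#'   is the integer mode index along x.
#' @param radius Disc radius for `"disc"`.
#' @param r_in,r_out Annulus radii.
#' @param width Interface width of the tanh profiles.
#' @return A `field_state`.
#' @export
field_fixtures <- function(kind = c("uniform", "single_mode", "disc",
                                    "annulus", "phobic_wall"),
                           grid, value = 0.5, eta_bar = 0.5, k_mode = 2,
                           eps_mode = 1e-4, radius = 20, r_in = 10,
                           r_out = 20, width = 1.5) {
  kind <- match.arg(kind)
  nx <- grid$nx; ny <- grid$ny
  zero <- matrix(0, nx, ny)
  cx <- (nx / 2) * grid$dx; cy <- (ny / 2) * grid$dx
  st <- switch(kind,
    uniform = field_state(matrix(value, nx, ny), zero, grid = grid),
    single_mode = {
      x <- (seq_len(nx) - 1) * grid$dx
      kx <- 2 * pi * k_mode / (nx * grid$dx)
      eta <- matrix(eta_bar + eps_mode * cos(kx * x), nx, ny)
      field_state(eta, zero, grid = grid)
    },
    disc = {
      r <- grid_radius(grid, cx, cy)
      field_state(0.5 * (1 - tanh((r - radius) / width)), zero, grid = grid)
    },
    annulus = {
      r <- grid_radius(grid, cx, cy)
      eta <- 0.5 * (tanh((r - r_in) / width) - tanh((r - r_out) / width))
      field_state(eta, zero, grid = grid)
    },
    phobic_wall = {
      eta <- matrix(1, nx, ny)
      phi <- matrix(-1, nx, ny)
      ## hydrophilic stripes at mid-domain and at the periodic seam, so
      ## the two half-domains are genuinely separated on the torus
      i <- seq_len(nx)
      wall <- abs(i - nx / 2) <= 2 | i <= 2 | i >= nx - 1
      phi[wall, ] <- 1
      chi <- zero
      chi[seq.int(4, floor(nx / 2) - 4), ] <- 1
      field_state(eta, phi, chi = list(chi), grid = grid)
    })
  st
}
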