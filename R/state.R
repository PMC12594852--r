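#' Construct a field state
#'
#' Bundles the simulator's grids: the complex order parameter `eta`, the
#' amphiphilicity field `phi` (`phi > 0` hydrophilic, `phi < 0`
#' hydrophobic) and one or more nucleic-acid concentration fields `chi`.
#'
#' @param eta,phi Numeric matrices of identical dimension.
#' @param chi List of nonnegative numeric matrices (possibly empty).
#' @param t Simulation time.
#' @param grid The `grid_spec` the fields live on.
#' @return An object of class `field_state`.
#' @export
field_state <- function(eta, phi, chi = list(), t = 0, grid) {
  st <- list(t = t, eta = eta, phi = phi, chi = chi, grid = grid)
  class(st) <- "field_state"
  validate_field_state(st)
  st
}

validate_field_state <- function(st) {
  g <- st$grid
  dims <- c(g$nx, g$ny)
  chk <- function(m, nm) {
    if (!is.matrix(m) || !all(dim(m) == dims))
      stop(sprintf("field '%s' must be a %d x %d matrix", nm, dims[1], dims[2]))
    if (!all(is.finite(m))) stop(sprintf("field '%s' contains non-finite values", nm))
  }
  chk(st$eta, "eta")
  chk(st$phi, "phi")
  for (i in seq_along(st$chi)) {
    chk(st$chi[[i]], paste0("chi_", i))
    if (min(st$chi[[i]]) < 0)
      stop(sprintf("chi_%d must be nonnegative", i))
  }
  invisible(st)
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> t = %g on %d x %d grid; %d chi species\n",
              x$t, x$grid$nx, x$grid$ny, length(x$chi)))
  cat(sprintf("  eta in [%.3g, %.3g], phi in [%.3g, %.3g]\n",
              min(x$eta), max(x$eta), min(x$phi), max(x$phi)))
  invisible(x)
}

#' Initialise the order-parameter fields
#'
#' In the default `preformed_droplet_surface_dna` mode the complex field
#' is a smoothed (tanh) disc of amplitude `min(1, zeta_protein / psi_c)`
#' centred on the domain plus a complexation seed band at the droplet
#' surface (complexes form first where the nucleic-acid coat meets the
#' protein droplet), each nucleic-acid species is an annular Gaussian
#' coat centred on the droplet interface carrying total mass
#' `zeta_dna * area(domain)`, and the amphiphilicity field is seeded
#' noise around `phi_bias`. Identical seeds reproduce bit-identical
#' states.
#'
#' @param grid A `grid_spec`.
#' @param ic An `initial_condition`.
#' @param params A `model_params` (supplies `psi_c` and the number of
#'   `chi` species through `k_bind`).
#' @return A `field_state` at `t = 0`.
#' @examples
#' g <- grid_spec(64, 64)
#' st <- init_state(g, initial_condition(droplet_radius = 14), model_params())
#' @export
init_state <- function(grid, ic, params) {
  stopifnot(inherits(grid, "grid_spec"), inherits(ic, "initial_condition"),
            inherits(params, "model_params"))
  lmin <- min(grid$nx, grid$ny) * grid$dx
  n_species <- length(params$k_bind)
  zeta_dna <- ic$zeta_dna
  if (length(zeta_dna) == 1 && n_species > 1)
    zeta_dna <- rep(zeta_dna, n_species)
  if (length(zeta_dna) != n_species)
    stop("length(zeta_dna) must match the number of chi species (length(k_bind))")

  amp <- min(1, ic$zeta_protein / params$psi_c)
  bg <- max(0, ic$zeta_protein - params$psi_c)
  noise <- with_seed(ic$seed, {
    list(eta = matrix(stats::rnorm(grid$nx * grid$ny), grid$nx, grid$ny),
         phi = matrix(stats::rnorm(grid$nx * grid$ny), grid$nx, grid$ny))
  })

  if (ic$mode == "preformed_droplet_surface_dna") {
    if (ic$droplet_radius >= lmin / 2)
      stop("droplet_radius must be smaller than half the domain")
    cx <- (grid$nx / 2) * grid$dx
    cy <- (grid$ny / 2) * grid$dx
    r <- grid_radius(grid, cx, cy)
    delta <- max(grid$dx, params$eps_eta * sqrt(2 / params$w_eta))
    disc <- 0.5 * (1 - tanh((r - ic$droplet_radius) / delta))
    seed_band <- exp(-0.5 * ((r - ic$droplet_radius) / ic$seed_width)^2)
    eta <- pmin(1, bg + (amp - bg) * disc + ic$surface_seed * amp * seed_band) +
      ic$noise_amp * noise$eta
    chi_mode <- rep(ic$chi_mode, length.out = n_species)
    chi <- lapply(seq_len(n_species), function(s) {
      if (zeta_dna[s] == 0) return(matrix(0, grid$nx, grid$ny))
      if (chi_mode[s] == "uniform")
        return(matrix(zeta_dna[s], grid$nx, grid$ny))
      r_coat <- ic$droplet_radius + ic$chi_offset
      ring <- exp(-0.5 * ((r - r_coat) / ic$ring_width)^2)
      ring * (zeta_dna[s] * grid_area(grid) / (sum(ring) * grid$dx^2))
    })
  } else {
    eta <- amp + ic$noise_amp * noise$eta
    chi <- lapply(seq_len(n_species), function(s)
      matrix(zeta_dna[s], grid$nx, grid$ny))
  }
  phi <- ic$phi_bias + ic$noise_amp * noise$phi
  field_state(eta = eta, phi = phi, chi = chi, t = 0, grid = grid)
}

## Dense-phase indicator s(eta) = eta^2 used throughout the functional.
s_eta <- function(eta) eta^2

## Clamped variant for transport gating (eta may transiently exceed 1).
s_eta_clamped <- function(eta) pmin(1, pmax(0, eta))^2

## Sigmoidal hydrophobicity gate.
gate_sigmoid <- function(x) 1 / (1 + exp(-x))

## Total mass of a field in grid units.
field_mass <- function(m, grid) sum(m) * grid$dx^2
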