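#' Phase-field model parameters
#'
#' Collects all constants of the three-order-parameter model of hollow
#' co-condensate formation. The complex order parameter `eta` follows
#' conserved Ohta--Kawasaki dynamics, the amphiphilicity field `phi`
#' relaxes non-conserved (Allen--Cahn) dynamics inside the dense phase,
#' and each nucleic-acid concentration field `chi` is transported by
#' gated drift--diffusion toward its local binding equilibrium.
#'
#' @param psi_c Critical volume fraction of the protein--nucleic-acid
#'   complex required for phase separation, in (0, 1). Inversely related
#'   to binding affinity: the initial complex level is
#'   `min(1, zeta_protein / psi_c)`, so raising `psi_c` pushes the seeded
#'   droplet below the phase-separation threshold.
#' @param b1 Buffer-contact asymmetry of the complex's hydrophilic versus
#'   hydrophobic domains. Rewards hydrophilic alignment (`phi > 0`) at
#'   dense--dilute interfaces; in the default configuration it is what
#'   destabilises the seeded droplet interior into a shell enclosing a
#'   dilute lumen.
#' @param b2 Core hydrophobicity coupling: deep inside the dense phase
#'   the complex buries its hydrophilic motifs, so `phi` is driven
#'   negative where the saturating core indicator `tanh(eta^6)` is large.
#' @param eps_eta,eps_phi Interface-width coefficients (their squares
#'   multiply the gradient penalties).
#' @param w_eta Depth of the double well `w_eta * eta^2 (1 - eta)^2`.
#' @param w_phi Depth of the amphiphilicity double well (quartic in `phi`),
#'   active mainly inside the dense phase.
#' @param phi_well_floor Residual weight of the `phi` well in the dilute
#'   phase (keeps the amphiphilicity field bounded where no complex is
#'   present).
#' @param alpha Ohta--Kawasaki long-range strength. Enters the dynamics
#'   as a relaxation `-alpha * (eta - mean(eta))` that suppresses
#'   unbounded coarsening and selects a finite structural length.
#' @param m_eta,m_phi Mobilities of `eta` and `phi`. `m_phi = 0` freezes
#'   the amphiphilicity field.
#' @param d_chi Bare diffusivity scale of the nucleic-acid fields.
#' @param xi Softness of the sigmoidal hydrophobicity gate
#'   `g(phi) = 1 / (1 + exp(phi / xi))`. The default is soft: the shell
#'   is an amphiphilic mixture rather than purely hydrophobic, so bound
#'   nucleic acid retains partial mobility and affinity there.
#' @param kappa Partition strength: the local binding equilibrium of
#'   species `s` is `K_s = 1 + kappa * k_bind[s] * A(eta, phi)` with the
#'   coupling-mode-dependent affinity field `A`.
#' @param eta_free,xi_free Midpoint and softness of the dilute-phase gate
#'   `sigma((eta_free - eta) / xi_free)` for unbound nucleic acid: free
#'   molecules diffuse in the dilute phase but cannot cross the dense
#'   shell except by complex-mediated (binding-gated) transport.
#' @param gamma_if Interfacial-affinity scale of the `"both"` coupling
#'   mode: the amphiphilic protein--RNA copolymer partitions to the
#'   dense--dilute interface with affinity `min(1.5, gamma_if |grad eta|^2)`.
#' @param coupling_mode `"hydrophobic_only"` (DNA moves within, and
#'   partitions to, hydrophobic dense regions) or `"both"` (the
#'   amphiphilic protein--RNA copolymer moves through hydrophilic and
#'   hydrophobic regions alike and partitions to the dense--dilute
#'   interfaces).
#' @param k_bind Binding-affinity coefficient, one per `chi` species.
#' @param dt Time step of the semi-implicit spectral scheme.
#' @param stab_eta,stab_phi Linear stabilisation constants of the
#'   semi-implicit splitting; defaults scale with the well depths.
#' @param seed Integer seed for any stochastic forcing (reserved; the
#'   dynamics themselves are deterministic).
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params()
#' p$psi_c
#' @export
model_params <- function(psi_c = 0.85,
                         b1 = 0.14,
                         b2 = 0.7,
                         eps_eta = sqrt(4),
                         eps_phi = sqrt(0.5),
                         w_eta = 4.2,
                         w_phi = 0.05,
                         alpha = 0.006,
                         m_eta = 1,
                         m_phi = 3,
                         d_chi = 0.5,
                         phi_well_floor = 0.1,
                         xi = 1.0,
                         kappa = 15,
                         eta_free = 0.25,
                         xi_free = 0.1,
                         gamma_if = 20,
                         coupling_mode = c("hydrophobic_only", "both"),
                         k_bind = 1,
                         dt = 0.2,
                         stab_eta = NULL,
                         stab_phi = NULL,
                         seed = 1L) {
  coupling_mode <- match.arg(coupling_mode)
  p <- list(psi_c = psi_c, b1 = b1, b2 = b2,
            eps_eta = eps_eta, eps_phi = eps_phi,
            w_eta = w_eta, w_phi = w_phi, alpha = alpha,
            m_eta = m_eta, m_phi = m_phi, d_chi = d_chi,
            phi_well_floor = phi_well_floor,
            xi = xi, kappa = kappa, eta_free = eta_free, xi_free = xi_free,
            gamma_if = gamma_if, coupling_mode = coupling_mode,
            k_bind = as.numeric(k_bind), dt = dt,
            stab_eta = if (is.null(stab_eta)) 5 * w_eta else stab_eta,
            stab_phi = if (is.null(stab_phi)) 2 * w_phi else stab_phi,
            seed = as.integer(seed))
  validate_model_params(p)
  class(p) <- "model_params"
  p
}

validate_model_params <- function(p) {
  num <- c("psi_c", "b1", "b2", "eps_eta", "eps_phi", "w_eta", "w_phi",
           "alpha", "m_eta", "m_phi", "d_chi", "phi_well_floor", "xi",
           "kappa", "eta_free", "xi_free", "gamma_if", "dt",
           "stab_eta", "stab_phi")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop(sprintf("parameter '%s' must be a finite number", f))
  }
  if (p$psi_c <= 0 || p$psi_c >= 1) stop("psi_c must lie in (0, 1)")
  if (p$dt <= 0) stop("dt must be positive")
  if (p$m_eta < 0 || p$m_phi < 0 || p$d_chi < 0)
    stop("mobilities must be nonnegative")
  if (p$xi <= 0) stop("xi must be positive")
  if (length(p$k_bind) < 1 || any(!is.finite(p$k_bind)) || any(p$k_bind < 0))
    stop("k_bind must be nonnegative and finite (one entry per chi species)")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  psi_c = %g, b1 = %g, b2 = %g, alpha = %g\n",
              x$psi_c, x$b1, x$b2, x$alpha))
  cat(sprintf("  wells: w_eta = %g, w_phi = %g; widths: eps_eta = %g, eps_phi = %g\n",
              x$w_eta, x$w_phi, x$eps_eta, x$eps_phi))
  cat(sprintf("  mobilities: m_eta = %g, m_phi = %g, d_chi = %g\n",
              x$m_eta, x$m_phi, x$d_chi))
  cat(sprintf("  coupling: %s, k_bind = [%s], kappa = %g, xi = %g\n",
              x$coupling_mode, paste(x$k_bind, collapse = ", "), x$kappa, x$xi))
  cat(sprintf("  dt = %g, seed = %d\n", x$dt, x$seed))
  invisible(x)
}

#' Initial condition of a simulation
#'
#' The default mode seeds a preformed protein droplet whose surface is
#' coated with nucleic acid, mirroring the experimental starting point in
#' which condensates form first and DNA decorates their surface before
#' infiltrating.
#'
#' @param mode `"preformed_droplet_surface_dna"` (tanh disc of complex
#'   with an annular nucleic-acid coat at its interface) or
#'   `"uniform_mix"` (spatially uniform levels plus noise).
#' @param zeta_protein Initial protein level (dimensionless, >= 0). The
#'   seeded complex amplitude is `min(1, zeta_protein / psi_c)`; protein
#'   in excess of `psi_c` remains as a dispersed background level
#'   `zeta_protein - psi_c`.
#' @param zeta_dna Initial nucleic-acid level(s), one per species.
#' @param chi_mode Initial placement per species: `"coat"` (annular coat
#'   at the droplet surface, the default) or `"uniform"` (dispersed in
#'   the bath, as for a species introduced after condensate formation).
#' @param droplet_radius Radius of the seeded droplet in grid units.
#' @param ring_width Gaussian width of the surface coat in grid units.
#' @param chi_offset Radial offset of the nucleic-acid coat relative to
#'   the droplet interface, in grid units. Slightly negative by default:
#'   complex formation draws the surface-bound nucleic acid just inside
#'   the droplet periphery before the shell closes.
#' @param surface_seed Amplitude, as a fraction of the droplet amplitude,
#'   of the complexation seed at the droplet surface: nucleic acid coats
#'   the droplet, so complex formation starts in a band at the interface.
#' @param seed_width Gaussian width of the complexation seed band.
#' @param noise_amp Amplitude of the seeded perturbation.
#' @param phi_bias Initial mean of the amphiphilicity field. Slightly
#'   positive by default: freshly formed complexes expose hydrophilic
#'   motifs.
#' @param seed Integer RNG seed for the initial noise.
#' @return An object of class `initial_condition`.
#' @examples
#' ic <- initial_condition(zeta_protein = 0.17, zeta_dna = 0.05)
#' @export
initial_condition <- function(mode = c("preformed_droplet_surface_dna", "uniform_mix"),
                              zeta_protein = 0.17,
                              zeta_dna = 0.05,
                              chi_mode = "coat",
                              droplet_radius = 40,
                              ring_width = 3,
                              chi_offset = -14,
                              surface_seed = 0.7,
                              seed_width = 6,
                              noise_amp = 0.01,
                              phi_bias = 0.15,
                              seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(zeta_protein) || zeta_protein < 0)
    stop("zeta_protein must be >= 0")
  if (any(!is.numeric(zeta_dna)) || any(zeta_dna < 0))
    stop("zeta_dna must be >= 0 elementwise")
  if (droplet_radius <= 0) stop("droplet_radius must be positive")
  if (ring_width <= 0) stop("ring_width must be positive")
  if (noise_amp < 0) stop("noise_amp must be >= 0")
  if (surface_seed < 0) stop("surface_seed must be >= 0")
  if (seed_width <= 0) stop("seed_width must be positive")
  if (!all(chi_mode %in% c("coat", "uniform")))
    stop("chi_mode entries must be 'coat' or 'uniform'")
  ic <- list(mode = mode, zeta_protein = zeta_protein,
             zeta_dna = as.numeric(zeta_dna), chi_mode = chi_mode,
             droplet_radius = droplet_radius, ring_width = ring_width,
             chi_offset = chi_offset,
             surface_seed = surface_seed, seed_width = seed_width,
             noise_amp = noise_amp, phi_bias = phi_bias,
             seed = as.integer(seed))
  class(ic) <- "initial_condition"
  ic
}

#' @export
print.initial_condition <- function(x, ...) {
  cat(sprintf("<initial_condition> mode = %s\n", x$mode))
  cat(sprintf("  zeta_protein = %g, zeta_dna = [%s]\n",
              x$zeta_protein, paste(x$zeta_dna, collapse = ", ")))
  cat(sprintf("  droplet_radius = %g, ring_width = %g, noise_amp = %g, phi_bias = %g, seed = %d\n",
              x$droplet_radius, x$ring_width, x$noise_amp, x$phi_bias, x$seed))
  invisible(x)
}

## Evaluate expr with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
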