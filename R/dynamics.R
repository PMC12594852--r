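## Semi-implicit Fourier-spectral time integration of the coupled
## eta / phi / chi dynamics.
##
##   d eta / dt = m_eta * Lap( dF/d eta ) - alpha * (eta - mean(eta))
##   d phi / dt = - m_phi * dF/d phi
##   d chi / dt = div( M_chi ( grad chi - chi grad ln K ) )
##
## Stiff linear operators are treated implicitly with a constant-
## coefficient (stabilised) splitting; all nonlinear terms are explicit.

## Local (non-Laplacian) part of dF/deta.
## Saturating dense-phase indicator for the coupling terms:
## s_c ~ eta^2 below the dense well, -> 1 smoothly above it, so the
## couplings never extrapolate beyond a unit complex fraction.
s_couple <- function(eta) sqrt(tanh(eta^4))

## d s_couple / d eta, with the removable 0/0 at eta = 0 guarded.
ds_couple <- function(eta) {
  t4 <- tanh(eta^4)
  ifelse(abs(eta) < 1e-10, 0, 2 * eta^3 * (1 - t4^2) / sqrt(pmax(t4, 1e-300)))
}

## Interface indicator q = 4 s_c (1 - s_c), unit maximum at the
## dense-dilute interface, vanishing in both bulk phases.
q_interface <- function(eta) {
  sc <- s_couple(eta)
  4 * sc * (1 - sc)
}

## Core-hydrophobicity indicator h = tanh(eta^6): negligible below the
## interface, ~1 in the dense core.
h_core <- function(eta) tanh(eta^6)

mu_eta_local <- function(eta, phi, gradsq_phi, params) {
  sc <- s_couple(eta)
  dq <- 4 * (1 - 2 * sc) * ds_couple(eta)
  dh <- 6 * eta^5 * (1 - tanh(eta^6)^2)
  2 * params$w_eta * eta * (1 - eta) * (1 - 2 * eta) +
    2 * eta * ((params$w_phi / 4) * (phi^2 - 1)^2 +
                 (params$eps_phi^2 / 2) * gradsq_phi) -
    params$b1 * phi * dq +
    params$b2 * phi * dh
}

## Local part of dF/dphi (excludes -eps_phi^2 div(s grad phi)).
fphi_local <- function(eta, phi, params) {
  s <- s_eta(eta)
  (s + params$phi_well_floor) * params$w_phi * (phi^3 - phi) -
    params$b1 * q_interface(eta) + params$b2 * h_core(eta)
}

#' Advance a field state by one time step
#'
#' One step of the semi-implicit Fourier-spectral scheme: the conserved
#' Ohta--Kawasaki dynamics of `eta`, non-conserved relaxation of `phi`
#' and flux-form drift--diffusion of each `chi` species (see
#' [chi_transport()]). Total `eta` mass and total `chi` mass are
#' conserved to round-off.
#'
#' @param state A `field_state`.
#' @param params A `model_params`.
#' @return The advanced `field_state` (time incremented by `params$dt`),
#'   with attribute `"clipped_chi"` recording any negative-concentration
#'   mass clipped per species.
#' @export
step_state <- function(state, params) {
  g <- state$grid
  dt <- params$dt
  eta <- state$eta
  phi <- state$phi

  phihat <- fft2(phi)
  dphix <- ifft2_re(1i * g$kx * phihat)
  dphiy <- ifft2_re(1i * g$ky * phihat)
  gradsq_phi <- dphix^2 + dphiy^2

  ## --- eta: conserved dynamics, implicit in eps^2 k^4, stab k^2, alpha ---
  etahat <- fft2(eta)
  gl <- mu_eta_local(eta, phi, gradsq_phi, params) - params$stab_eta * eta
  alpha_k <- matrix(params$alpha, g$nx, g$ny)
  alpha_k[1, 1] <- 0
  den <- 1 + dt * (params$m_eta * (params$eps_eta^2 * g$k4 +
                                     params$stab_eta * g$k2) + alpha_k)
  etahat_new <- (etahat - dt * params$m_eta * g$k2 * fft2(gl)) / den
  eta_new <- ifft2_re(etahat_new)

  ## --- phi: Allen-Cahn relaxation with stabilised implicit Laplacian ---
  if (params$m_phi > 0) {
    s <- s_eta(eta)
    smax <- max(1, max(s))
    sxhat <- fft2(s * dphix)
    syhat <- fft2(s * dphiy)
    div_sgrad_hat <- 1i * g$kx * sxhat + 1i * g$ky * syhat
    nhat <- fft2(fphi_local(eta, phi, params) - params$stab_phi * phi) -
      params$eps_phi^2 * div_sgrad_hat -
      params$eps_phi^2 * smax * g$k2 * phihat
    den_phi <- 1 + dt * params$m_phi * (params$eps_phi^2 * smax * g$k2 +
                                          params$stab_phi)
    phi_new <- ifft2_re((phihat - dt * params$m_phi * nhat) / den_phi)
  } else {
    phi_new <- phi
  }

  t_new <- state$t + dt
  if (!all(is.finite(eta_new)))
    stop(sprintf("divergence in field 'eta' at t = %g", t_new))
  if (!all(is.finite(phi_new)))
    stop(sprintf("divergence in field 'phi' at t = %g", t_new))

  st <- state
  st$eta <- eta_new
  st$phi <- phi_new
  st$t <- t_new

  clipped <- numeric(length(state$chi))
  if (length(state$chi) > 0 && params$d_chi > 0) {
    tr <- chi_transport(st, params, dt = dt)
    st$chi <- tr$chi
    clipped <- tr$clipped
    for (i in seq_along(st$chi))
      if (!all(is.finite(st$chi[[i]])))
        stop(sprintf("divergence in field 'chi_%d' at t = %g", i, t_new))
  }
  attr(st, "clipped_chi") <- clipped
  st
}

## Periodic shift of a matrix by (di, dj): element [i, j] of the result
## is m[i + di, j + dj] (wrapped).
shift_mat <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  i <- ((seq_len(n1) - 1 + di) %% n1) + 1
  j <- ((seq_len(n2) - 1 + dj) %% n2) + 1
  m[i, j, drop = FALSE]
}

## Coupling-mode-dependent affinity field A(eta, phi): what the bound
## species partitions to. In hydrophobic_only mode affinity requires
## dense complex (Hill-type saturation, half-saturation 0.1) in a
## (softly) hydrophobic environment; in both mode the amphiphilic
## copolymer partitions to the dense-dilute interface (|grad eta|^2).
chi_affinity <- function(eta, phi, params, grid = NULL) {
  sc <- s_eta_clamped(eta)
  if (params$coupling_mode == "hydrophobic_only") {
    (sc^2 / (sc^2 + 0.004)) * gate_sigmoid(-phi / params$xi)
  } else {
    dx <- if (is.null(grid)) 1 else grid$dx
    gx <- (shift_mat(eta, 1, 0) - shift_mat(eta, -1, 0)) / (2 * dx)
    gy <- (shift_mat(eta, 0, 1) - shift_mat(eta, 0, -1)) / (2 * dx)
    pmin(1.5, params$gamma_if * (gx^2 + gy^2))
  }
}

## Coupling-mode-dependent mobility gate g(phi).
chi_gate <- function(phi, params) {
  if (params$coupling_mode == "hydrophobic_only")
    gate_sigmoid(-phi / params$xi)
  else
    matrix(1, nrow(phi), ncol(phi))
}

## Dilute-phase gate for unbound nucleic acid: ~1 in the dilute phase,
## ~0 inside the dense shell.
chi_free_gate <- function(eta, params) {
  gate_sigmoid((params$eta_free - eta) / params$xi_free)
}

#' Transport the nucleic-acid fields
#'
#' Advances each `chi` species by conservative drift--diffusion
#' \deqn{\partial_t \chi = \nabla\cdot\big(M_\chi(\nabla\chi
#'   - \chi\,\nabla\ln K)\big),}
#' discretised in flux form (finite volumes on cell faces), so total mass
#' is conserved to round-off. The mobility
#' \deqn{M_\chi = d_\chi\,[\sigma((\eta_{free}-\eta)/\xi_{free})
#'   + k_{bind}\,s(\eta)\,g(\phi)]}
#' lets free nucleic acid diffuse in the dilute phase while transport
#' through the dense shell is complex-mediated: it requires binding
#' (`k_bind`) and, in `"hydrophobic_only"` mode, a (softly) hydrophobic
#' environment (\eqn{g(\phi) = \sigma(-\phi/\xi)}; \eqn{g = 1} in
#' `"both"` mode). The local binding equilibrium
#' \eqn{K = 1 + \kappa\,k_{bind}\,A(\eta,\phi)} makes
#' \eqn{\chi \propto K} the steady state, so strongly bound species
#' enrich where their affinity field \eqn{A} is high (dense hydrophobic
#' regions for protein--dsDNA complexes; the dense--dilute interface for
#' the amphiphilic protein--RNA copolymer).
#'
#' Negative concentrations produced by round-off are clipped to zero and
#' the clipped mass recorded.
#'
#' @param state A `field_state` (its `eta` and `phi` define the gates).
#' @param params A `model_params`.
#' @param dt Time interval to advance (defaults to `params$dt`);
#'   internally substepped for stability.
#' @return A list with `chi` (updated list of matrices) and `clipped`
#'   (clipped mass per species).
#' @export
chi_transport <- function(state, params, dt = params$dt) {
  g <- state$grid
  if (params$d_chi < 0) stop("d_chi must be nonnegative")
  gate <- chi_gate(state$phi, params)
  aff <- chi_affinity(state$eta, state$phi, params, grid = g)
  free <- chi_free_gate(state$eta, params)
  sc <- s_eta_clamped(state$eta)
  out <- state$chi
  clipped <- numeric(length(out))
  for (sp in seq_along(out)) {
    kb <- params$k_bind[sp]
    m <- params$d_chi * (free + kb * sc * gate)
    kfield <- 1 + params$kappa * kb * aff
    mk <- m * kfield
    dmax <- max(mk)
    if (dmax == 0) next
    nsub <- max(1L, ceiling(dt / (0.2 * g$dx^2 / dmax)))
    dts <- dt / nsub
    chi <- out[[sp]]
    ## harmonic face means: a sharp low-mobility barrier must block flux
    hmean <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
    mk_xr <- hmean(mk, shift_mat(mk, 1, 0))
    mk_yr <- hmean(mk, shift_mat(mk, 0, 1))
    for (it in seq_len(nsub)) {
      u <- chi / kfield
      fx <- mk_xr * (shift_mat(u, 1, 0) - u) / g$dx
      fy <- mk_yr * (shift_mat(u, 0, 1) - u) / g$dx
      chi <- chi + dts * ((fx - shift_mat(fx, -1, 0)) +
                            (fy - shift_mat(fy, 0, -1))) / g$dx
    }
    neg <- chi < 0
    if (any(neg)) {
      clipped[sp] <- -sum(chi[neg]) * g$dx^2
      chi[neg] <- 0
    }
    out[[sp]] <- chi
  }
  list(chi = out, clipped = clipped)
}
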