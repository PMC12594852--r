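# Independent oracles used by the solver tests. These reimplement the
# dynamics plainly (explicit Euler in time) and morphology tests
# (queue-based flood fill) without touching the package's integrator.

# Spectral helpers local to the oracle.
or_k <- function(n, dx = 1) 2 * pi / (n * dx) * c(0:(n / 2), (-n / 2 + 1):(-1))

or_lap <- function(m, dx = 1) {
  nx <- nrow(m); ny <- ncol(m)
  kx <- matrix(or_k(nx, dx), nx, ny)
  ky <- matrix(or_k(ny, dx), nx, ny, byrow = TRUE)
  Re(stats::fft(stats::fft(m) * (-(kx^2 + ky^2)), inverse = TRUE)) / (nx * ny)
}

or_grad <- function(m, dx = 1) {
  nx <- nrow(m); ny <- ncol(m)
  kx <- matrix(or_k(nx, dx), nx, ny)
  ky <- matrix(or_k(ny, dx), nx, ny, byrow = TRUE)
  mh <- stats::fft(m)
  list(x = Re(stats::fft(1i * kx * mh, inverse = TRUE)) / (nx * ny),
       y = Re(stats::fft(1i * ky * mh, inverse = TRUE)) / (nx * ny))
}

or_div <- function(fx, fy, dx = 1) {
  nx <- nrow(fx); ny <- ncol(fx)
  kx <- matrix(or_k(nx, dx), nx, ny)
  ky <- matrix(or_k(ny, dx), nx, ny, byrow = TRUE)
  Re(stats::fft(1i * kx * stats::fft(fx) + 1i * ky * stats::fft(fy),
                inverse = TRUE)) / (nx * ny)
}

# Chemical potential dF/deta written out from the functional
# (saturating coupling indicators s_c = sqrt(tanh(eta^4)),
# q = 4 s_c (1 - s_c), h = tanh(eta^6)).
or_mu_eta <- function(eta, phi, p, dx = 1) {
  gp <- or_grad(phi, dx)
  t4 <- tanh(eta^4)
  sc <- sqrt(t4)
  dsc <- ifelse(abs(eta) < 1e-10, 0,
                2 * eta^3 * (1 - t4^2) / sqrt(pmax(t4, 1e-300)))
  dq <- 4 * (1 - 2 * sc) * dsc
  dh <- 6 * eta^5 * (1 - tanh(eta^6)^2)
  2 * p$w_eta * eta * (1 - eta) * (1 - 2 * eta) +
    2 * eta * ((p$w_phi / 4) * (phi^2 - 1)^2 +
                 (p$eps_phi^2 / 2) * (gp$x^2 + gp$y^2)) -
    p$b1 * phi * dq + p$b2 * phi * dh -
    p$eps_eta^2 * or_lap(eta, dx)
}

or_f_phi <- function(eta, phi, p, dx = 1) {
  s <- eta^2
  sc <- sqrt(tanh(eta^4))
  gp <- or_grad(phi, dx)
  (s + p$phi_well_floor) * p$w_phi * (phi^3 - phi) -
    p$b1 * 4 * sc * (1 - sc) + p$b2 * tanh(eta^6) -
    p$eps_phi^2 * or_div(s * gp$x, s * gp$y, dx)
}

# One explicit-Euler step of the full coupled dynamics.
oracle_explicit_step <- function(st, p, dt) {
  g <- st$grid
  eta <- st$eta; phi <- st$phi
  mu <- or_mu_eta(eta, phi, p, g$dx)
  eta_new <- eta + dt * (p$m_eta * or_lap(mu, g$dx) -
                           p$alpha * (eta - mean(eta)))
  phi_new <- if (p$m_phi > 0) phi - dt * p$m_phi * or_f_phi(eta, phi, p, g$dx)
             else phi
  chi_new <- lapply(seq_along(st$chi), function(sp)
    oracle_chi_step(st$chi[[sp]], eta, phi, p, sp, dt, g$dx))
  st$eta <- eta_new; st$phi <- phi_new; st$chi <- chi_new
  st$t <- st$t + dt
  st
}

# Flux-form drift-diffusion step for one chi species (plain loops over
# faces via shifted copies, independent of the package implementation).
oracle_chi_step <- function(chi, eta, phi, p, sp, dt, dx = 1) {
  rot0 <- function(x, di, dj) {
    n1 <- nrow(x); n2 <- ncol(x)
    x[((seq_len(n1) - 1 + di) %% n1) + 1, ((seq_len(n2) - 1 + dj) %% n2) + 1]
  }
  sc <- pmin(1, pmax(0, eta))^2
  gmode <- if (p$coupling_mode == "hydrophobic_only")
    1 / (1 + exp(phi / p$xi)) else matrix(1, nrow(phi), ncol(phi))
  aff <- if (p$coupling_mode == "hydrophobic_only") {
    (sc^2 / (sc^2 + 0.004)) * gmode
  } else {
    gxe <- (rot0(eta, 1, 0) - rot0(eta, -1, 0)) / (2 * dx)
    gye <- (rot0(eta, 0, 1) - rot0(eta, 0, -1)) / (2 * dx)
    pmin(1.5, p$gamma_if * (gxe^2 + gye^2))
  }
  kb <- p$k_bind[sp]
  free <- 1 / (1 + exp(-(p$eta_free - eta) / p$xi_free))
  m <- p$d_chi * (free + kb * sc * gmode)
  kf <- 1 + p$kappa * kb * aff
  u <- chi / kf
  mk <- m * kf
  rot <- function(x, di, dj) {
    n1 <- nrow(x); n2 <- ncol(x)
    x[((seq_len(n1) - 1 + di) %% n1) + 1, ((seq_len(n2) - 1 + dj) %% n2) + 1]
  }
  hm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  fx <- hm(mk, rot(mk, 1, 0)) * (rot(u, 1, 0) - u) / dx
  fy <- hm(mk, rot(mk, 0, 1)) * (rot(u, 0, 1) - u) / dx
  chi + dt * ((fx - rot(fx, -1, 0)) + (fy - rot(fy, 0, -1))) / dx
}

# Queue-based flood fill from the matrix border over the dilute mask;
# returns TRUE when some unreached dilute pocket of at least hole_min
# cells exists next to a dense component of at least a_min cells.
oracle_is_hollow <- function(eta, eta_dense = 0.5, a_min = 100, hole_min = 20) {
  dense <- eta > eta_dense
  nx <- nrow(dense); ny <- ncol(dense)
  reach <- matrix(FALSE, nx, ny)
  queue <- which(!dense & (row(dense) %in% c(1, nx) | col(dense) %in% c(1, ny)))
  reach[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    i <- (cur - 1) %% nx + 1; j <- (cur - 1) %/% nx + 1
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
      if (!dense[ii, jj] && !reach[ii, jj]) {
        reach[ii, jj] <- TRUE
        queue <- c(queue, (jj - 1) * nx + ii)
      }
    }
  }
  cavity <- !dense & !reach
  if (sum(cavity) < hole_min) return(FALSE)
  # require a sizeable dense structure
  sum(dense) >= a_min
}

# Compact parameter/grid builders shared by solver tests.
small_params <- function(...) model_params(...)

pure_ch_params <- function(w_eta = 1, eps_eta = 1, m_eta = 1, alpha = 0,
                           dt = 0.01) {
  model_params(w_eta = w_eta, eps_eta = eps_eta, m_eta = m_eta,
               alpha = alpha, w_phi = 0, b1 = 0, b2 = 0, m_phi = 0,
               d_chi = 0, phi_well_floor = 0, dt = dt,
               stab_eta = 2 * w_eta)
}

# Smooth random state on a small grid (low-frequency modes only).
smooth_state <- function(grid, seed, n_chi = 0, base = 0.4, amp = 0.15) {
  set.seed(seed)
  nx <- grid$nx; ny <- grid$ny
  x <- 2 * pi * (0:(nx - 1)) / nx
  y <- 2 * pi * (0:(ny - 1)) / ny
  mk <- function(off) {
    m <- matrix(off, nx, ny)
    for (kx in 0:2) for (ky in 0:2) {
      if (kx == 0 && ky == 0) next
      m <- m + amp * stats::rnorm(1) / (kx + ky) *
        outer(cos(kx * x + stats::runif(1, 0, 2 * pi)),
              cos(ky * y + stats::runif(1, 0, 2 * pi)))
    }
    m
  }
  chi <- lapply(seq_len(n_chi), function(i) pmax(mk(0.5), 0.01))
  field_state(mk(base), mk(0), chi = chi, grid = grid)
}
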