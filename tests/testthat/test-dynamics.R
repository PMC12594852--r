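# Solver verification: determinism, conservation, fixed points, energy
# dissipation, the linear dispersion relation and an explicit-Euler
# time-integration oracle.

test_that("identical configurations and seeds give bit-identical states", {
  g <- grid_spec(32, 32)
  p <- model_params(dt = 0.1)
  ic <- initial_condition(zeta_protein = 0.17, zeta_dna = 0.05,
                          droplet_radius = 8, seed = 42L)
  s1 <- init_state(g, ic, p)
  s2 <- init_state(g, ic, p)
  expect_identical(s1$eta, s2$eta)
  expect_identical(s1$phi, s2$phi)
  expect_identical(s1$chi, s2$chi)
  for (i in 1:5) { s1 <- step_state(s1, p); s2 <- step_state(s2, p) }
  expect_identical(s1$eta, s2$eta)
  expect_identical(s1$chi[[1]], s2$chi[[1]])
})

test_that("initial conditions respect mass and amplitude contracts", {
  g <- grid_spec(64, 64)
  p <- model_params()
  ic <- initial_condition(zeta_protein = 0.17, zeta_dna = 0.3,
                          droplet_radius = 14, seed = 3L)
  st <- init_state(g, ic, p)
  expect_equal(sum(st$chi[[1]]) * g$dx^2, 0.3 * 64 * 64, tolerance = 1e-9)

  ic0 <- initial_condition(zeta_protein = 0, zeta_dna = 0,
                           droplet_radius = 14, noise_amp = 0.005)
  st0 <- init_state(g, ic0, p)
  expect_lte(max(abs(st0$eta)), 0.005 * 6)  # noise_amp scale only

  expect_error(init_state(g, initial_condition(droplet_radius = 40), p),
               "half the domain")
  expect_error(initial_condition(zeta_protein = -1), ">= 0")
})

test_that("total eta and chi mass are conserved over long runs", {
  g <- grid_spec(64, 64)
  p <- model_params(dt = 0.2, alpha = 0.006)
  ic <- initial_condition(zeta_protein = 0.17, zeta_dna = 0.05,
                          droplet_radius = 16, seed = 1L)
  st <- init_state(g, ic, p)
  m_eta0 <- sum(st$eta)
  m_chi0 <- sum(st$chi[[1]])
  for (i in 1:2000) st <- step_state(st, p)
  expect_lt(abs(sum(st$eta) - m_eta0) / abs(m_eta0), 1e-10)
  expect_lt(abs(sum(st$chi[[1]]) - m_chi0) / m_chi0, 1e-8)
})

test_that("a uniform state at the well minima is a fixed point", {
  g <- grid_spec(32, 32)
  p <- model_params(dt = 0.1)
  st <- field_state(matrix(0, 32, 32), matrix(1, 32, 32),
                    chi = list(matrix(0.2, 32, 32)), grid = g)
  st2 <- st
  for (i in 1:100) st2 <- step_state(st2, p)
  expect_lt(max(abs(st2$eta - st$eta)), 1e-12)
  expect_lt(max(abs(st2$phi - st$phi)), 1e-12)
  expect_lt(max(abs(st2$chi[[1]] - st$chi[[1]])), 1e-12)
})

test_that("free energy has the closed-form bulk value and penalises gradients", {
  g <- grid_spec(32, 32)
  p <- model_params(w_phi = 0, alpha = 0, b1 = 0, b2 = 0)
  area <- 32 * 32
  st <- field_state(matrix(0.3, 32, 32), matrix(0, 32, 32), grid = g)
  expect_equal(free_energy(st, p), p$w_eta * 0.3^2 * 0.7^2 * area,
               tolerance = 1e-12)

  st0 <- field_state(matrix(0, 32, 32), matrix(0, 32, 32), grid = g)
  expect_equal(free_energy(st0, p), 0)

  ## perturbing a uniform state at a well minimum raises the energy
  x <- 2 * pi * (0:31) / 32
  pert <- field_state(matrix(0 + 0.01 * cos(x), 32, 32),
                      matrix(0, 32, 32), grid = g)
  expect_gt(free_energy(pert, p), free_energy(st0, p))
  expect_error(free_energy(field_state(matrix(0, 32, 32) * NA,
                                       matrix(0, 32, 32), grid = g), p))
})

test_that("free energy is non-increasing for the conserved gradient flow", {
  g <- grid_spec(64, 64)
  p <- pure_ch_params(w_eta = 1, eps_eta = 1, dt = 0.05)
  st <- smooth_state(g, seed = 9)
  e_prev <- free_energy(st, p)
  for (save in 1:10) {
    for (i in 1:40) st <- step_state(st, p)
    e <- free_energy(st, p)
    expect_lte(e, e_prev * (1 + sign(e_prev) * 1e-10) + 1e-12)
    e_prev <- e
  }
})

test_that("small perturbations grow at the analytic dispersion rate", {
  g <- grid_spec(64, 64)
  eta_bar <- 0.5
  p <- pure_ch_params(w_eta = 1, eps_eta = 1, dt = 0.01)
  for (k_mode in c(2, 3)) {
    st <- field_fixtures("single_mode", g, eta_bar = eta_bar,
                         k_mode = k_mode, eps_mode = 1e-5)
    k <- 2 * pi * k_mode / 64
    fpp <- p$w_eta * (2 - 12 * eta_bar + 12 * eta_bar^2)
    sigma <- -p$m_eta * k^2 * (fpp + p$eps_eta^2 * k^2) - p$alpha
    x <- 2 * pi * (0:63) / 64
    amp <- function(s) 2 * mean(s$eta[, 1] * cos(k_mode * x))
    a0 <- amp(st)
    n_steps <- 200
    for (i in 1:n_steps) st <- step_state(st, p)
    measured <- log(amp(st) / a0) / (n_steps * p$dt)
    expect_lt(abs(measured - sigma) / abs(sigma), 0.02)
  }
})

test_that("the semi-implicit step matches an explicit-Euler oracle", {
  g <- grid_spec(16, 16)
  p <- model_params(dt = 1e-4, alpha = 0.006, d_chi = 0.5)
  for (seed in 1:3) {
    st <- smooth_state(g, seed = seed, n_chi = 1)
    pkg <- step_state(st, p)
    orc <- st
    for (i in 1:100) orc <- oracle_explicit_step(orc, p, p$dt / 100)
    expect_lt(max(abs(pkg$eta - orc$eta)), 1e-6)
    expect_lt(max(abs(pkg$phi - orc$phi)), 1e-6)
    expect_lt(max(abs(pkg$chi[[1]] - orc$chi[[1]])), 1e-6)
  }
})

test_that("divergence is reported with the failing field and time", {
  g <- grid_spec(16, 16)
  p <- model_params(dt = 50, stab_eta = 0, w_eta = 50)  # deliberately unstable
  st <- smooth_state(g, seed = 1)
  expr <- try({
    for (i in 1:500) st <- step_state(st, p)
  }, silent = TRUE)
  expect_true(inherits(expr, "try-error"))
  expect_match(attr(expr, "condition")$message, "divergence in field")
})

test_that("chi relaxes diffusively where ungated and respects hydrophilic walls", {
  g <- grid_spec(32, 32)
  ## both mode, uniform dense eta: pure diffusion toward uniform chi
  p <- model_params(coupling_mode = "both", dt = 0.1, d_chi = 0.5)
  chi0 <- matrix(0, 32, 32); chi0[1:16, ] <- 1
  st <- field_state(matrix(1, 32, 32), matrix(0, 32, 32),
                    chi = list(chi0), grid = g)
  v_prev <- stats::var(as.vector(chi0))
  for (rep in 1:5) {
    for (i in 1:200) {
      tr <- chi_transport(st, p)
      st$chi <- tr$chi
    }
    v <- stats::var(as.vector(st$chi[[1]]))
    expect_lt(v, v_prev)
    v_prev <- v
  }
  expect_lt(v_prev, 0.01)

  ## hydrophobic_only mode: a phi > 0 stripe wall blocks transport
  p2 <- model_params(coupling_mode = "hydrophobic_only", xi = 0.1,
                     dt = 0.1, d_chi = 0.5)
  g2 <- grid_spec(64, 64)
  wall <- field_fixtures("phobic_wall", g2)
  m0 <- sum(wall$chi[[1]])
  right_half <- (32 + 4):(64 - 3)  # between the mid wall and the seam wall
  for (i in 1:400) {
    tr <- chi_transport(wall, p2)
    wall$chi <- tr$chi
  }
  crossed <- sum(wall$chi[[1]][right_half, ])
  expect_lt(crossed / m0, 0.01)
  expect_equal(sum(wall$chi[[1]]), m0, tolerance = 1e-10)
})
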