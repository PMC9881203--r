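# naive O(n^2) time-origin-averaged MSD oracle
msd_oracle <- function(X, dt) {
  n <- nrow(X)
  vapply(0:(n - 1), function(m) {
    if (m == 0) return(0)
    d <- X[(1 + m):n, , drop = FALSE] - X[1:(n - m), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
}

test_that("FFT mean squared displacement matches the direct average", {
  set.seed(2)
  n <- 64
  X <- apply(matrix(rnorm(n * 3), n, 3), 2, cumsum)
  co <- array(X, c(n, 1, 3))
  tr <- trajectory((0:(n - 1)) * 0.1, co, box = 1e6, chain_id = 1L,
                   wrapped = FALSE)
  m <- compute_msd(tr)
  expect_equal(m$msd, msd_oracle(X, 0.1), tolerance = 1e-10)
  # ballistic motion: MSD(lag) = (v * lag)^2 exactly
  v <- c(1.5, -0.7, 0.3)
  Xb <- outer(0:(n - 1), v) * 0.1
  trb <- trajectory((0:(n - 1)) * 0.1, array(Xb, c(n, 1, 3)), 1e6, 1L,
                    wrapped = FALSE)
  mb <- compute_msd(trb)
  expect_equal(mb$msd, sum(v^2) * mb$lags^2, tolerance = 1e-8)
  expect_error(compute_msd(trajectory((0:4) * 0.1, array(0, c(5, 1, 3)),
                                      10, 1L)), "10 frames")
})

test_that("unwrapping restores the free-space displacement statistics", {
  free <- gen_brownian_trajectory(5, 3, 1.5, box = 1e5, dt = 0.05,
                                  n_frames = 200, seed = 7)
  wrapped <- gen_brownian_trajectory(5, 3, 1.5, box = 40, dt = 0.05,
                                     n_frames = 200, seed = 7)
  # same RNG stream: displacements identical, only the box images differ
  m_free <- compute_msd(free)
  m_wrap <- compute_msd(wrapped)
  expect_equal(m_wrap$msd, m_free$msd, tolerance = 1e-5)
})

test_that("diffusion slope fit inverts an exact Einstein relation", {
  lags <- seq(0, 10, by = 0.05)
  msd <- structure(list(lags = lags, msd = 6 * 1.37 * lags + 4.2),
                   class = "msd_result")
  f <- fit_diffusion(msd)
  expect_equal(f$D, 1.37, tolerance = 1e-10)
  expect_equal(f$intercept, 4.2, tolerance = 1e-8)
  expect_error(fit_diffusion(msd, window = c(0.3, 50)), "range error")
  expect_error(fit_diffusion(msd, window = c(3, 3.01)), "range error")
})

test_that("Brownian trajectories return their input diffusion coefficient", {
  errs <- vapply(1:5, function(s) {
    tr <- gen_brownian_trajectory(30, 4, 1.5, box = 300, dt = 0.05,
                                  n_frames = 1000, seed = 40 + s)
    D <- fit_diffusion(compute_msd(tr))$D
    abs(D - 1.5) / 1.5
  }, numeric(1))
  expect_lt(mean(errs), 0.08)
  expect_lt(max(errs), 0.2)
})

test_that("periodic-box correction matches its closed form and direction", {
  kB <- 1.380649e-23
  L <- 170; eta <- 8; T <- 300
  expected <- kB * T * 2.837297 / (6 * pi * eta * 1e-3 * L * 1e-10) * 1e11
  expect_equal(pbc_correction(1.0, T, eta, L) - 1.0, expected,
               tolerance = 1e-12)
  # the correction shrinks with box size and grows with temperature
  expect_gt(pbc_correction(1, 300, 8, 100), pbc_correction(1, 300, 8, 300))
  expect_gt(pbc_correction(1, 350, 8, 170), pbc_correction(1, 300, 8, 170))
  expect_error(pbc_correction(1, 300, -1, 170), "invalid parameter")
})

test_that("rotational diffusion is recovered from rigid-rotor orientations", {
  errs <- vapply(1:3, function(s) {
    tr <- gen_rigid_rotor_trajectory(D_t = 1, D_r = 0.05,
                                     site_radii = seq(2, 15, length.out = 10),
                                     dt = 0.1, n_frames = 4000, seed = 60 + s)
    abs(rotational_diffusion(tr)$D_r - 0.05) / 0.05
  }, numeric(1))
  expect_lt(mean(errs), 0.10)
  # a non-rotating body reports zero rotational diffusion
  tr0 <- gen_rigid_rotor_trajectory(D_t = 1, D_r = 0,
                                    site_radii = seq(2, 15, length.out = 10),
                                    dt = 0.1, n_frames = 500, seed = 1)
  expect_equal(rotational_diffusion(tr0)$D_r, 0)
})

test_that("apparent diffusion reduces to translation for point scatterers", {
  q <- seq(0.19, 1.9, length.out = 8)
  a0 <- apparent_DG(1.5, 0.3, site_radii = rep(0, 5), q_values = q)
  expect_equal(a0$D_G_app, 1.5, tolerance = 1e-8)
  a1 <- apparent_DG(1.5, 0, site_radii = seq(2, 15, length.out = 10),
                    q_values = q)
  expect_equal(a1$D_G_app, 1.5, tolerance = 1e-8)
  # rotation of extended bodies only adds apparent mobility
  a2 <- apparent_DG(1.5, 0.05, site_radii = seq(2, 15, length.out = 10),
                    q_values = q)
  a3 <- apparent_DG(1.5, 0.2, site_radii = seq(2, 15, length.out = 10),
                    q_values = q)
  expect_gt(a2$D_G_app, 1.5)
  expect_gt(a3$D_G_app, a2$D_G_app)
})

test_that("apparent diffusion agrees with a simulated scattering function", {
  radii <- seq(2, 15, length.out = 10)
  tr <- gen_rigid_rotor_trajectory(D_t = 1, D_r = 0.05, site_radii = radii,
                                   dt = 0.1, n_frames = 4000, seed = 3)
  co <- tr$coords
  qs <- c(0.3, 0.5)
  lag_idx <- seq(3, 20)          # 0.3 - 2 ns window
  D_sim <- vapply(qs, function(q) {
    isf <- vapply(lag_idx, function(m) {
      n <- dim(co)[1]
      d <- sqrt(rowSums((co[(1 + m):n, , ] - co[1:(n - m), , ])^2,
                        dims = 2))
      mean(sin(q * d) / (q * d))
    }, numeric(1))
    fit <- stats::lm(log(isf) ~ I(lag_idx * 0.1))
    -unname(coef(fit)[2]) / q^2
  }, numeric(1))
  pred <- apparent_DG(1, 0.05, radii, q_values = qs,
                      t_window = c(0.3, 2))$D_app
  expect_lt(max(abs(pred - D_sim) / D_sim), 0.10)
})

test_that("Green-Kubo viscosity reproduces the analytic OU value", {
  ps <- gen_ou_pressure(sigma = 8, tau_c = 0.05, dt = 0.005,
                        n_steps = 60000, seed = 5)
  eta_true <- attr(ps, "eta_true")
  v <- green_kubo_viscosity(ps, T = 300, V = 170^3, cutoff = 0.5)
  expect_lt(abs(v$eta - eta_true) / eta_true, 0.10)
  # linearity in volume (the unit convention's only free scale)
  v2 <- green_kubo_viscosity(ps, T = 300, V = 2 * 170^3, cutoff = 0.5)
  expect_equal(v2$eta, 2 * v$eta, tolerance = 1e-12)
  expect_error(green_kubo_viscosity(ps, 300, 170^3, cutoff = 1e6),
               "range error")
  expect_error(green_kubo_viscosity(ps[c("time", "P1")], 300, 170^3, 0.5),
               "2 pressure components")
})

test_that("a constant pressure signal carries zero shear viscosity", {
  ps <- data.frame(time = (0:999) * 0.005,
                   P1 = rep(3, 1000), P2 = rep(-1, 1000))
  v <- green_kubo_viscosity(ps, 300, 170^3, 0.5)
  expect_equal(v$eta, 0, tolerance = 1e-12)
})

test_that("cell-list contacts equal the brute-force reference", {
  for (s in 1:10) {
    tr <- gen_brownian_trajectory(10, 50, 1, box = 60, dt = 0.1,
                                  n_frames = 2, seed = 200 + s)
    a <- contact_stats(tr, method = "cell_list")
    b <- contact_stats(tr, method = "brute_force")
    expect_equal(a$n_contacts, b$n_contacts)
    expect_equal(a$class_tally, b$class_tally)
    ka <- with(a$contacts, sort(paste(i, j)))
    kb <- with(b$contacts, sort(paste(i, j)))
    expect_equal(ka, kb)
  }
})

test_that("contacts respect the minimum-image convention and charge classes", {
  # two chains straddling the periodic boundary: raw distance 97, true 3
  co <- array(0, c(1, 4, 3))
  co[1, 1, ] <- c(1, 50, 50)    # chain 1 (|q| = 0.3: hydrophilic)
  co[1, 2, ] <- c(5, 50, 50)    # chain 1
  co[1, 3, ] <- c(98, 50, 50)   # chain 2, within cutoff of atom 1 via image
  co[1, 4, ] <- c(60, 50, 50)   # chain 2, far from everything
  tr <- trajectory(0, co, box = 100, chain_id = c(1, 1, 2, 2),
                   charge = c(0.3, 0.0, -0.1, 0.5))
  cs <- contact_stats(tr, cutoff = 4, method = "brute_force")
  expect_equal(cs$n_contacts, 1L)
  expect_equal(cs$contacts$i, 1L)
  expect_equal(cs$contacts$j, 3L)
  expect_equal(cs$contacts$dist, 3, tolerance = 1e-12)
  expect_equal(as.character(cs$contacts$class), "Phi-Pho")
  expect_equal(sum(cs$class_tally), cs$n_contacts)
  cs2 <- contact_stats(tr, cutoff = 4)
  expect_equal(cs2$n_contacts, 1L)
})

test_that("cluster sizes match an independent union-find oracle", {
  for (s in 1:5) {
    tr <- gen_brownian_trajectory(12, 30, 1, box = 70, dt = 0.1,
                                  n_frames = 2, seed = 400 + s)
    cs <- contact_stats(tr)
    expect_equal(cluster_proteins(cs),
                 uf_components(12, as.matrix(cs$partner_pairs)))
  }
  # fully separated chains are all singletons
  co <- array(0, c(1, 3, 3))
  co[1, , 1] <- c(5, 50, 95) - 50
  co[1, , ] <- co[1, , ] + 50
  tr <- trajectory(0, co, box = 300, chain_id = 1:3, charge = rep(0, 3))
  expect_equal(cluster_proteins(tr, cutoff = 4), rep(1L, 3))
})
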