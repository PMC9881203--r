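test_that("jump-diffusion fit recovers noiseless parameters exactly", {
  q <- seq(0.19, 1.9, length.out = 16)
  w <- jump_diffusion_width(q, 1.5, 0.2)
  fit <- fit_jump_diffusion(q, w)
  expect_lt(abs(fit$D - 1.5), 1e-6)
  expect_lt(abs(fit$tau - 0.2), 1e-6)
  # Fickian data: tau collapses to zero
  w2 <- pt_constants$hbar_ueV_ns * 2.0 * q^2
  fit2 <- fit_jump_diffusion(q, w2)
  expect_lt(abs(fit2$D - 2.0), 1e-6)
  expect_lt(fit2$tau, 1e-6)
  expect_error(fit_jump_diffusion(q[1:2], w[1:2]), "insufficient data")
  expect_error(fit_jump_diffusion(q, -w), "widths")
})

test_that("jump-diffusion errors are calibrated against Monte Carlo", {
  q <- seq(0.19, 1.9, length.out = 16)
  w0 <- jump_diffusion_width(q, 1.5, 0.2)
  set.seed(99)
  Ds <- ses <- numeric(100)
  for (r in 1:100) {
    w <- w0 * (1 + 0.02 * rnorm(16))
    f <- fit_jump_diffusion(q, w, width_errors = 0.02 * w0)
    Ds[r] <- f$D; ses[r] <- f$D_se
  }
  expect_lt(abs(mean(Ds) - 1.5) / 1.5, 0.02)
  # reported curvature error consistent with the replicate spread (factor 2)
  ratio <- sd(Ds) / mean(ses)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("spectrum fit recovers generation truth under 2% noise", {
  sp <- gen_qens_spectrum(truth_params(), noise_rel = 0.02, seed = 42)
  fr <- fit_spectrum(sp, resolution_model(), fit_config())
  p <- fr$params
  expect_lt(abs(p$D_G - 1.5) / 1.5, 0.10)
  expect_lt(abs(p$tau_G - 0.1) / 0.1, 0.20)
  expect_lt(abs(p$D_L - 30) / 30, 0.20)
  expect_lt(abs(p$tau_L - 180) / 180, 0.20)
  expect_lt(abs(p$r_L - 2) / 2, 0.20)
  expect_lt(abs(p$p_L - 0.4) / 0.4, 0.20)
  expect_true(fr$converged)
})

test_that("noiseless spectra are fitted essentially exactly", {
  sp <- gen_qens_spectrum(truth_params(), noise_rel = 0, seed = 1)
  fr <- fit_spectrum(sp, resolution_model(), fit_config())
  expect_lt(abs(fr$params$D_G - 1.5) / 1.5, 1e-3)
  expect_lt(abs(fr$params$tau_L - 180) / 180, 1e-2)
  expect_lt(fr$redchi2, 1e-4)
})

test_that("two-stage and global strategies agree on noiseless data", {
  sp <- gen_qens_spectrum(truth_params(), noise_rel = 0, seed = 1)
  f1 <- fit_spectrum(sp, resolution_model(), fit_config("two_stage"))
  f2 <- fit_spectrum(sp, resolution_model(), fit_config("global"))
  for (nm in c("D_G", "tau_G", "D_L", "tau_L", "r_L", "p_L"))
    expect_lt(abs(f1$params[[nm]] - f2$params[[nm]]) /
                max(abs(f1$params[[nm]]), 1e-12), 0.01)
})

test_that("a solvent-free truth yields phi consistent with zero", {
  sp <- gen_qens_spectrum(truth_params(), noise_rel = 0.02, seed = 17)
  cfg <- fit_config("global", include_solvent = TRUE, gamma_D2O = 5)
  # phi * amplitude is a flat direction when the truth has no solvent, so
  # the optimiser may report hitting the iteration cap; only the fitted
  # solvent contribution matters here
  fr <- suppressWarnings(fit_spectrum(sp, resolution_model(), cfg))
  phi_amp <- fr$params$phi * mean(fr$params$solvent_amplitude)
  # the effective solvent contribution is negligible vs the protein signal
  expect_lt(phi_amp, 0.05 * mean(fr$params$intensity))
})

test_that("fits are invariant under uniform intensity rescaling", {
  sp <- gen_qens_spectrum(truth_params(), noise_rel = 0.02, seed = 5)
  sc <- qens_spectrum(sp$temperature, sp$q_values, sp$energy_grid,
                      sp$intensities * 37, sp$uncertainties * 37)
  f1 <- fit_spectrum(sp, resolution_model(), fit_config())
  f2 <- fit_spectrum(sc, resolution_model(), fit_config())
  # the fitter normalises the count scale internally, so any residual
  # scale dependence is optimiser termination noise: orders of magnitude
  # below the ~1% statistical errors, but not bitwise zero
  for (nm in c("D_G", "tau_G", "D_L", "tau_L", "r_L", "p_L"))
    expect_equal(f1$params[[nm]], f2$params[[nm]], tolerance = 1e-4)
  expect_equal(f2$params$intensity, 37 * f1$params$intensity,
               tolerance = 1e-4)
})

test_that("temperature series fitting tracks a decreasing D_G", {
  res <- resolution_model()
  Ts <- seq(300, 345, length.out = 10)
  D_true <- seq(2.2, 0.6, length.out = 10)
  spectra <- lapply(1:10, function(i)
    gen_qens_spectrum(truth_params(D_G = D_true[i]), res, T = Ts[i],
                      noise_rel = 0.02, seed = 300 + i))
  series <- fit_temperature_series(spectra, res, fit_config())
  expect_equal(nrow(series), 10)
  expect_true(all(series$converged))
  expect_equal(cor(series$D_G, D_true, method = "spearman"), 1)
  expect_error(fit_temperature_series(spectra[1], res), "insufficient data")
})

test_that("identical spectra give identical fitted parameters", {
  res <- resolution_model()
  sp <- gen_qens_spectrum(truth_params(), res, T = 300, noise_rel = 0.02,
                          seed = 9)
  series <- fit_temperature_series(list(sp, sp), res, fit_config())
  expect_equal(series$D_G[1], series$D_G[2], tolerance = 1e-8)
  expect_equal(series$p_L[1], series$p_L[2], tolerance = 1e-8)
})

test_that("zero uncertainties are rejected as a weighting error", {
  sp <- gen_qens_spectrum(truth_params(), noise_rel = 0.02, seed = 3)
  sp$uncertainties[1, 1] <- 0
  expect_error(fit_spectrum(sp, resolution_model()), "weighting error")
})
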