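test_that("lorentzian has the textbook peak, hwhm and unit integral", {
  expect_equal(lorentzian(0, 1), 1 / pi)
  for (g in c(0.3, 1, 4.7))
    expect_equal(lorentzian(g, g), 0.5 * lorentzian(0, g))
  # quadrature oracle for the normalisation
  quad <- stats::integrate(lorentzian, -1000, 1000, hwhm = 1)$value
  expect_lt(abs(quad - 1), 1e-3)
  expect_error(lorentzian(0, 0), "invalid parameter")
  expect_error(lorentzian(0, -1), "invalid parameter")
})

test_that("jump-diffusion width has Fickian and plateau limits", {
  hbar <- pt_constants$hbar_ueV_ns
  expect_equal(jump_diffusion_width(1, 1, 0), hbar)
  # q -> infinity plateau is hbar/tau
  expect_equal(jump_diffusion_width(1e6, 5, 0.5), hbar / 0.5, tolerance = 1e-6)
  # jump rate D q^2/(1 + D q^2 tau) = 1/ns at q=1, D=2, tau=0.5
  expect_equal(jump_diffusion_width(1, 2, 0.5), hbar)
  q <- seq(0.1, 3, length.out = 40)
  expect_true(all(diff(jump_diffusion_width(q, 1.5, 0.2)) > 0))
  expect_error(jump_diffusion_width(-1, 1, 0), "invalid parameter")
  expect_error(jump_diffusion_width(1, -1, 0), "invalid parameter")
})

test_that("EISF equals 1 at q = 0 and p_L = 1, and p_L at the j1 root", {
  expect_equal(eisf(0, 3.2, 0.17), 1.0)
  q <- seq(0, 3, by = 0.05)
  expect_equal(eisf(q, 5, 1), rep(1, length(q)))
  # first positive root of j1 located by a bracketing oracle
  j1 <- function(x) sin(x) / x^2 - cos(x) / x
  root <- stats::uniroot(j1, c(4, 5), tol = 1e-12)$root
  for (p in c(0, 0.4, 0.9)) {
    r_L <- 2.5
    expect_equal(eisf(root / r_L, r_L, p), p, tolerance = 1e-9)
  }
  # non-increasing up to the first root, bounded in [0, 1]
  r_L <- 2
  qq <- seq(0, root / r_L, length.out = 50)
  a <- eisf(qq, r_L, 0.3)
  expect_true(all(diff(a) <= 1e-12))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(eisf(1, 2, 1.5), "invalid parameter")
  expect_error(eisf(1, -2, 0.5), "invalid parameter")
})

test_that("detailed balance is unity at E = 0 and satisfies the pair identity", {
  expect_equal(detailed_balance(0, 300), 1.0)
  E <- c(-31, -5, 2, 31)
  expect_equal(detailed_balance(E, 310) * detailed_balance(-E, 310),
               rep(1, 4))
  # high-precision evaluation at the instrument band edge
  expect_equal(detailed_balance(31, 300),
               exp(-31 / (2 * 86.17333 * 300)), tolerance = 1e-12)
  expect_equal(detailed_balance(c(1, 2), 300, mode = "off"), c(1, 1))
  expect_error(detailed_balance(1, -10), "invalid parameter")
})

test_that("model spectrum conserves intensity under a delta resolution", {
  # conservation is a continuum property: the grid must resolve the
  # narrowest line (hwhm ~ 0.065 ueV here) and the band must dwarf the
  # broadest, hence the fine spacing and the narrow widths
  E <- (-3100:3100) / 100
  imp <- as.numeric(abs(E) < 1e-9)
  res <- resolution_model("numeric", profiles = matrix(imp, 1, length(E),
                                                       byrow = TRUE),
                          energy_grid = E)
  p <- spectrum_params(2.7, 0.4, 0.05, 3, 50, 2, 0.4)
  S <- model_spectrum(p, res, q_values = 0.5, energy_grid = E, T = 300,
                      db_mode = "off")
  expect_equal(sum(S[1, ]) * 0.01, 2.7, tolerance = 0.01)
})

test_that("convolving two Lorentzians yields the summed width", {
  E <- seq(-80, 80, by = 0.2)   # > 20x wider than a + b
  a <- 1.2; b <- 2.3
  res <- resolution_model("numeric", profiles = matrix(lorentzian(E, a), 1,
                                                       length(E), byrow = TRUE),
                          energy_grid = E)
  # protein term reduced to one Lorentzian of width b: p_L = 1 puts all the
  # weight on the global line, whose width is set through D with tau = 0
  p <- spectrum_params(1, b / pt_constants$hbar_ueV_ns, 0, 0.1, 0, 2, 1)
  S <- model_spectrum(p, res, 1, E, 300, db_mode = "off")
  fit <- minpack.lm::nls.lm(par = c(I = 1, w = 2),
                            fn = function(pp) S[1, ] - pp[1] * lorentzian(E, pp[2]))
  expect_lt(abs(fit$par[2] - (a + b)) / (a + b), 0.01)
})

test_that("model spectrum is linear in intensity and solvent amplitude", {
  g <- default_instrument_grid()
  res <- resolution_model()
  set.seed(4)
  for (i in 1:3) {
    I1 <- runif(1, 0.5, 2); I2 <- runif(1, 0.5, 2)
    base <- list(D_G = 1.5, tau_G = 0.1, D_L = 30, tau_L = 180, r_L = 2,
                 p_L = 0.4)
    p1 <- do.call(spectrum_params, c(list(intensity = I1), base))
    p2 <- do.call(spectrum_params, c(list(intensity = I2), base))
    p12 <- do.call(spectrum_params, c(list(intensity = I1 + I2), base))
    S1 <- model_spectrum(p1, res, g$q_values, g$energy_grid, 300)
    S2 <- model_spectrum(p2, res, g$q_values, g$energy_grid, 300)
    S12 <- model_spectrum(p12, res, g$q_values, g$energy_grid, 300)
    expect_equal(S1 + S2, S12, tolerance = 1e-10)
  }
})

test_that("zero protein intensity leaves only the solvent line", {
  g <- default_instrument_grid()
  res <- resolution_model()
  p <- spectrum_params(0, 1.5, 0.1, 30, 180, 2, 0.4, phi = 1,
                       solvent_amplitude = 0.8, gamma_D2O = 4)
  S <- model_spectrum(p, res, g$q_values, g$energy_grid, 300)
  # compare against the directly convolved solvent term
  dE <- 0.25
  db <- detailed_balance(g$energy_grid, 300)
  sigma <- 0.75 / (2 * sqrt(2 * log(2)))
  kern <- exp(-g$energy_grid^2 / (2 * sigma^2))
  kern <- kern / (sum(kern) * dE)
  ref <- db * stats::convolve(0.8 * lorentzian(g$energy_grid, 4), rev(kern),
                              type = "open")[125:(125 + 248)] * dE
  expect_equal(S[1, ], ref, tolerance = 1e-8)
  expect_true(all(S >= 0))
})

test_that("grid violations are rejected", {
  expect_error(qens_spectrum(300, c(0.2, 0.5), c(0, 0.1, 0.3),
                             matrix(1, 2, 3), matrix(1, 2, 3)),
               "grid error")
  E1 <- seq(-5, 5, 0.5); E2 <- seq(-5, 5, 0.25)
  res <- resolution_model("numeric", profiles = matrix(1, 1, length(E2)),
                          energy_grid = E2)
  p <- spectrum_params(1, 1, 0.1, 30, 180, 2, 0.4)
  expect_error(model_spectrum(p, res, 1, E1, 300), "grid error")
})
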