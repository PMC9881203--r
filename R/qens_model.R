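#' Lorentzian line shape
#'
#' Normalised Lorentzian density used for the quasi-elastic broadening of
#' both the global and local diffusive processes and for the heavy-water
#' solvent contribution.
#'
#' @param E energy transfer, micro-eV (vector).
#' @param hwhm half width at half maximum, micro-eV (> 0).
#' @return density in 1/micro-eV; unit integral over the real line.
#' @export
lorentzian <- function(E, hwhm) {
  if (!is.numeric(hwhm) || length(hwhm) != 1L || !is.finite(hwhm) || hwhm <= 0)
    stop("invalid parameter: hwhm must be a single positive number")
  (hwhm / pi) / (E^2 + hwhm^2)
}

#' Jump-diffusion half width
#'
#' Half width at half maximum of the quasi-elastic Lorentzian under the
#' jump-diffusion model: Fickian (hbar*D*q^2) at low q, saturating to the
#' plateau hbar/tau at high q.
#'
#' @param q momentum transfer, 1/Angstrom (vector, > 0).
#' @param D diffusion coefficient, Angstrom^2/ns (>= 0).
#' @param tau residence time, ns (>= 0).
#' @return hwhm in micro-eV.
#' @export
jump_diffusion_width <- function(q, D, tau) {
  if (any(q <= 0) || !is.finite(D) || D < 0 || !is.finite(tau) || tau < 0)
    stop("invalid parameter: q must be > 0 and D, tau must be >= 0")
  pt_constants$hbar_ueV_ns * D * q^2 / (1 + D * q^2 * tau)
}

#' Elastic incoherent structure factor
#'
#' Fixed-fraction plus diffusion-in-a-sphere (Volino-Dianoux) geometry:
#' a fraction \code{p_L} of atoms appears immobile on the accessible time
#' scale, the remainder explores a sphere of radius \code{r_L}.
#'
#' @param q momentum transfer, 1/Angstrom (vector, >= 0).
#' @param r_L confinement radius, Angstrom (> 0).
#' @param p_L fixed-atom fraction in [0, 1].
#' @return A0(q) in [p_L*(something), 1]; A0(0) = 1 by continuity.
#' @export
eisf <- function(q, r_L, p_L) {
  if (!is.finite(r_L) || r_L <= 0)
    stop("invalid parameter: r_L must be > 0")
  if (!is.finite(p_L) || p_L < 0 || p_L > 1)
    stop("invalid parameter: p_L must lie in [0, 1]")
  if (any(q < 0)) stop("invalid parameter: q must be >= 0")
  x <- q * r_L
  # 3 j1(x)/x -> 1 as x -> 0; j1(x) = sin(x)/x^2 - cos(x)/x
  f <- ifelse(x < 1e-6, 1 - x^2 / 10, 3 * (sin(x) / x^2 - cos(x) / x) / x)
  p_L + (1 - p_L) * f^2
}

#' Detailed balance factor
#'
#' Thermal asymmetry between the neutron energy-gain and energy-loss sides
#' of the spectrum. The symmetric convention exp(-E/(2 kB T)) is the
#' default; \code{mode} switches to the one-sided exp(-E/(kB T)) form or
#' turns the factor off.
#'
#' @param E energy transfer, micro-eV (vector).
#' @param T temperature, K (> 0).
#' @param mode one of "symmetric", "one-sided", "off".
#' @export
detailed_balance <- function(E, T, mode = c("symmetric", "one-sided", "off")) {
  mode <- match.arg(mode)
  if (!is.finite(T) || T <= 0) stop("invalid parameter: T must be > 0")
  switch(mode,
    symmetric   = exp(-E / (2 * pt_constants$kB_ueV_K * T)),
    `one-sided` = exp(-E / (pt_constants$kB_ueV_K * T)),
    off         = rep(1, length(E))
  )
}

# ---- domain-type constructors ------------------------------------------

#' QENS spectrum container
#'
#' S(q, E) with uncertainties at one temperature, on a uniform energy grid
#' symmetric about E = 0.
#'
#' @param temperature K.
#' @param q_values 1/Angstrom, ascending.
#' @param energy_grid micro-eV, uniform spacing.
#' @param intensities matrix |q| x |E|, non-negative.
#' @param uncertainties matrix |q| x |E|, strictly positive.
#' @param meta optional list of provenance (truth parameters for synthetic
#'   spectra, instrument name, ...).
#' @return an object of class \code{qens_spectrum}.
#' @export
qens_spectrum <- function(temperature, q_values, energy_grid, intensities,
                          uncertainties, meta = list()) {
  stopifnot(is.numeric(temperature), temperature > 0)
  if (is.unsorted(q_values, strictly = TRUE))
    stop("q_values must be strictly ascending")
  check_uniform_grid(energy_grid)
  intensities <- as.matrix(intensities)
  uncertainties <- as.matrix(uncertainties)
  if (!all(dim(intensities) == c(length(q_values), length(energy_grid))) ||
      !all(dim(uncertainties) == dim(intensities)))
    stop("grid error: intensities/uncertainties must be |q| x |E|")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (any(uncertainties <= 0)) stop("uncertainties must be > 0")
  structure(list(temperature = temperature, q_values = q_values,
                 energy_grid = energy_grid, intensities = intensities,
                 uncertainties = uncertainties, meta = meta),
            class = "qens_spectrum")
}

#' Instrument resolution model
#'
#' Either a Gaussian of given fwhm (micro-eV) or per-q numeric profiles
#' measured on the spectrum's energy grid. Numeric profiles are
#' renormalised to unit integral when discretised.
#'
#' @param kind "gaussian" or "numeric".
#' @param fwhm full width at half maximum, micro-eV (gaussian kind).
#' @param profiles matrix |q| x |E| (numeric kind).
#' @param energy_grid grid the numeric profiles are defined on.
#' @export
resolution_model <- function(kind = c("gaussian", "numeric"), fwhm = 0.75,
                             profiles = NULL, energy_grid = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (!is.finite(fwhm) || fwhm <= 0) stop("invalid parameter: fwhm must be > 0")
    structure(list(kind = "gaussian", fwhm = fwhm), class = "resolution_model")
  } else {
    if (is.null(profiles) || is.null(energy_grid))
      stop("numeric resolution requires profiles and energy_grid")
    check_uniform_grid(energy_grid)
    profiles <- as.matrix(profiles)
    if (ncol(profiles) != length(energy_grid))
      stop("grid error: profile columns must match energy_grid")
    structure(list(kind = "numeric", profiles = profiles,
                   energy_grid = energy_grid), class = "resolution_model")
  }
}

#' Model parameter bundle for the scattering function
#'
#' @param intensity per-q signal intensity I(q), >= 0 (scalar recycled).
#' @param D_G,tau_G global (translation+rotation) diffusion, Angstrom^2/ns,
#'   and residence time, ns.
#' @param D_L,tau_L local side-chain diffusion, Angstrom^2/ns, and residence
#'   time, ps.
#' @param r_L,p_L confinement radius (Angstrom) and fixed-atom fraction of
#'   the local-motion geometry.
#' @param phi solvent weight in [0, 1].
#' @param solvent_amplitude per-q solvent intensity.
#' @param gamma_D2O per-q Lorentzian hwhm of the heavy-water line, micro-eV.
#' @export
spectrum_params <- function(intensity, D_G, tau_G, D_L, tau_L, r_L, p_L,
                            phi = 0, solvent_amplitude = 0, gamma_D2O = 1) {
  stopifnot(all(intensity >= 0), D_G >= 0, tau_G >= 0, D_L >= 0, tau_L >= 0,
            r_L > 0, p_L >= 0, p_L <= 1, phi >= 0, phi <= 1)
  structure(list(intensity = intensity, D_G = D_G, tau_G = tau_G,
                 D_L = D_L, tau_L = tau_L, r_L = r_L, p_L = p_L,
                 phi = phi, solvent_amplitude = solvent_amplitude,
                 gamma_D2O = gamma_D2O),
            class = "spectrum_params")
}

# ---- grid helpers -------------------------------------------------------

check_uniform_grid <- function(energy_grid) {
  if (length(energy_grid) < 3L) stop("grid error: energy grid too short")
  d <- diff(energy_grid)
  if (any(abs(d - d[1]) > 1e-8 * abs(d[1])))
    stop("grid error: energy grid must be uniform")
  invisible(d[1])
}

#' Discrete zero-padded convolution on a uniform grid
#'
#' Convolves a signal with a kernel sampled on the same uniform grid; the
#' kernel is treated as a density (renormalised to unit integral) centred
#' on E = 0. Edges are zero-padded.
#'
#' @param signal numeric vector on the grid.
#' @param kernel numeric vector on the same grid.
#' @param dE grid spacing.
#' @keywords internal
convolve_uniform <- function(signal, kernel, dE) {
  n <- length(signal)
  if (length(kernel) != n) stop("grid error: kernel and signal length differ")
  kernel <- kernel / (sum(kernel) * dE)
  full <- stats::convolve(signal, rev(kernel), type = "open") * dE
  # central n samples; grid symmetric about 0 so the kernel centre is at
  # index (n+1)/2 for odd n (generators use odd grids)
  centre <- (n + 1L) %/% 2L
  full[centre:(centre + n - 1L)]
}

resolution_kernel <- function(resolution, energy_grid, q_index) {
  if (resolution$kind == "gaussian") {
    sigma <- resolution$fwhm / (2 * sqrt(2 * log(2)))
    exp(-energy_grid^2 / (2 * sigma^2))
  } else {
    if (length(resolution$energy_grid) != length(energy_grid) ||
        any(abs(resolution$energy_grid - energy_grid) > 1e-8))
      stop("grid error: resolution grid does not match spectrum grid")
    i <- min(q_index, nrow(resolution$profiles))
    resolution$profiles[i, ]
  }
}

#' Forward model of the experimental scattering function
#'
#' Evaluates, per q, the detailed-balance-weighted, resolution-convolved
#' sum of the protein term — elastic fraction A0(q) broadened only by the
#' global process, quasi-elastic fraction (1 - A0) broadened by global plus
#' local motion — and an optional heavy-water solvent Lorentzian:
#' \deqn{S(q,E) = DB(E,T) [ R(q,.) \otimes ( I(q)(A_0 L(\gamma_G) +
#'   (1-A_0) L(\gamma_G+\gamma_L)) + \phi a(q) L(\gamma_{D2O}) ) ]}
#' with both widths from the jump-diffusion model.
#'
#' @param params a \code{spectrum_params} object.
#' @param resolution a \code{resolution_model}.
#' @param q_values,energy_grid instrument grid (1/Angstrom, micro-eV).
#' @param T temperature, K.
#' @param db_mode detailed-balance convention, see [detailed_balance()].
#' @return matrix |q| x |E| of model intensities.
#' @export
model_spectrum <- function(params, resolution, q_values, energy_grid, T,
                           db_mode = "symmetric") {
  dE <- check_uniform_grid(energy_grid)
  nq <- length(q_values)
  I_q <- rep_len(params$intensity, nq)
  amp <- rep_len(params$solvent_amplitude, nq)
  gD2O <- rep_len(params$gamma_D2O, nq)
  db <- detailed_balance(energy_grid, T, db_mode)
  A0 <- eisf(q_values, params$r_L, params$p_L)
  gG <- jump_diffusion_width(q_values, params$D_G, params$tau_G)
  gL <- jump_diffusion_width(q_values, params$D_L, params$tau_L / 1000)
  out <- matrix(0, nq, length(energy_grid))
  for (i in seq_len(nq)) {
    protein <- I_q[i] * (A0[i] * safe_lorentzian(energy_grid, gG[i]) +
                         (1 - A0[i]) * safe_lorentzian(energy_grid, gG[i] + gL[i]))
    total <- protein
    if (params$phi > 0 && any(amp > 0))
      total <- total + params$phi * amp[i] * lorentzian(energy_grid, gD2O[i])
    kern <- resolution_kernel(resolution, energy_grid, i)
    out[i, ] <- db * convolve_uniform(total, kern, dE)
  }
  out
}

# Lorentzian that degrades gracefully to a discrete elastic line when the
# width collapses (D = 0): a delta is represented as 1/dE at E = 0.
safe_lorentzian <- function(E, hwhm) {
  if (hwhm <= 0) {
    d <- as.numeric(abs(E) < 1e-12)
    return(d / (sum(d) * (E[2] - E[1])))
  }
  lorentzian(E, hwhm)
}
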