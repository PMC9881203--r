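#' Default instrument grid of the backscattering emulation
#'
#' 16 q values covering 0.19-1.9 1/Angstrom and a symmetric energy grid
#' |E| <= 31 micro-eV at 0.25 micro-eV spacing, matching the IN16b-like
#' conditions the synthetic spectra emulate.
#'
#' @return list with \code{q_values} and \code{energy_grid}.
#' @export
default_instrument_grid <- function() {
  list(q_values = seq(0.19, 1.9, length.out = 16),
       energy_grid = seq(-31, 31, by = 0.25))
}

#' Generate a synthetic QENS spectrum
#'
#' Evaluates the forward model on the instrument grid and applies
#' multiplicative Gaussian noise of relative width \code{noise_rel}
#' (counting statistics at high counts); a "poisson-like" option scales
#' the relative error as 1/sqrt(intensity) instead. Uncertainties are set
#' to the true noise level. The truth parameters are stored in the
#' spectrum's \code{meta}.
#'
#' @param truth a \code{spectrum_params}.
#' @param resolution a \code{resolution_model} (default Gaussian,
#'   0.75 micro-eV fwhm).
#' @param q_values,energy_grid instrument grid (defaults:
#'   [default_instrument_grid()]).
#' @param T temperature, K.
#' @param noise_rel relative noise level (>= 0).
#' @param seed RNG seed; fixed seed gives identical output.
#' @param noise_model "gaussian-relative" or "poisson-like".
#' @param db_mode detailed-balance convention.
#' @return a \code{qens_spectrum}.
#' @export
gen_qens_spectrum <- function(truth, resolution = resolution_model(),
                              q_values = NULL, energy_grid = NULL, T = 300,
                              noise_rel = 0.02, seed = 1L,
                              noise_model = c("gaussian-relative",
                                              "poisson-like"),
                              db_mode = "symmetric") {
  noise_model <- match.arg(noise_model)
  if (noise_rel < 0) stop("invalid parameter: noise_rel must be >= 0")
  g <- default_instrument_grid()
  if (is.null(q_values)) q_values <- g$q_values
  if (is.null(energy_grid)) energy_grid <- g$energy_grid
  S <- model_spectrum(truth, resolution, q_values, energy_grid, T, db_mode)
  if (noise_model == "gaussian-relative") {
    sig <- noise_rel * S
  } else {
    sig <- noise_rel * sqrt(pmax(S, 0) * max(S))
  }
  if (noise_rel > 0) {
    set.seed(seed)
    S <- S * (1 + noise_rel * matrix(stats::rnorm(length(S)), nrow(S)))
    S[S < 0] <- 0
  }
  sig[sig <= 0] <- max(sig) * 1e-6 + 1e-12
  qens_spectrum(T, q_values, energy_grid, S, sig,
                meta = list(truth = truth, noise_rel = noise_rel,
                            seed = seed, db_mode = db_mode))
}

# random unit-ish rigid site cluster with distinct principal moments
random_sites <- function(n_atoms, radius, seed_offset = 0) {
  X <- matrix(stats::rnorm(n_atoms * 3), ncol = 3)
  X <- sweep(X, 2, c(1, 0.6, 0.3), `*`)   # anisotropic: distinct moments
  X <- X / max(sqrt(rowSums(X^2))) * radius
  sweep(X, 2, colMeans(X))
}

#' Generate a Brownian multi-chain trajectory
#'
#' Chain centres follow independent isotropic Gaussian displacements with
#' variance 2*D*dt per dimension (6*D*dt total); atoms ride rigidly on
#' their chain. Positions are stored wrapped into the periodic box.
#' Truth parameters land in \code{meta}.
#'
#' @param n_chains,atoms_per_chain system size.
#' @param D_per_chain diffusion coefficient(s), Angstrom^2/ns (recycled).
#' @param box edge length, Angstrom.
#' @param dt frame spacing, ns.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param chain_radius rigid-cluster radius, Angstrom.
#' @param charge_palette charges sampled per atom, e.
#' @return a \code{trajectory}.
#' @export
gen_brownian_trajectory <- function(n_chains, atoms_per_chain, D_per_chain,
                                    box, dt, n_frames, seed = 1L,
                                    chain_radius = 5,
                                    charge_palette = c(-0.4, -0.15, 0, 0.1, 0.35)) {
  stopifnot(n_chains > 0, atoms_per_chain > 0, box > 0, dt > 0, n_frames > 1)
  D <- rep_len(D_per_chain, n_chains)
  if (any(sqrt(6 * D * dt) > 0.1 * box))
    warning("stability: step displacement exceeds 10% of the box")
  set.seed(seed)
  n_atoms <- n_chains * atoms_per_chain
  chain_id <- rep(seq_len(n_chains), each = atoms_per_chain)
  charge <- sample(charge_palette, n_atoms, replace = TRUE)
  sites <- lapply(seq_len(n_chains), function(k)
    random_sites(atoms_per_chain, chain_radius))
  centres0 <- matrix(stats::runif(n_chains * 3, 0, box), ncol = 3)
  co <- array(0, c(n_frames, n_atoms, 3))
  centres <- centres0
  for (t in seq_len(n_frames)) {
    if (t > 1)
      centres <- centres + matrix(stats::rnorm(n_chains * 3), ncol = 3) *
        sqrt(2 * D * dt)
    for (k in seq_len(n_chains)) {
      idx <- which(chain_id == k)
      co[t, idx, ] <- sweep(sites[[k]], 2, centres[k, ], `+`) %% box
    }
  }
  trajectory(times = (seq_len(n_frames) - 1) * dt, coords = co,
             box = rep(box, 3), chain_id = chain_id,
             charge = charge, mass = rep(1, n_atoms), wrapped = TRUE,
             meta = list(D_truth = D, seed = seed, dt = dt))
}

rotation_matrix <- function(omega) {
  th <- sqrt(sum(omega^2))
  if (th < 1e-14) return(diag(3))
  k <- omega / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Generate a rigid-rotor trajectory
#'
#' One rigid body with isotropic translational diffusion D_t and
#' rotational diffusion D_r (small random rotation vectors, per-axis
#' variance 2*D_r*dt per step). Coordinates are stored unwrapped in a
#' large box. Truth parameters land in \code{meta}.
#'
#' @param D_t Angstrom^2/ns.
#' @param D_r 1/ns.
#' @param site_radii site distances from the centre of mass, Angstrom; a
#'   numeric vector (random anisotropic cluster scaled accordingly) — the
#'   generated sites reproduce these radii exactly.
#' @param dt ns.
#' @param n_frames frames.
#' @param seed RNG seed.
#' @return a \code{trajectory} with one chain.
#' @export
gen_rigid_rotor_trajectory <- function(D_t, D_r, site_radii, dt, n_frames,
                                       seed = 1L) {
  stopifnot(D_t >= 0, D_r >= 0, dt > 0, n_frames > 1, all(site_radii >= 0))
  set.seed(seed)
  n_sites <- length(site_radii)
  # anisotropic directions, exact radii
  dirs <- matrix(stats::rnorm(n_sites * 3), ncol = 3)
  dirs <- sweep(dirs, 2, c(1, 0.6, 0.3), `*`)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sites <- dirs * site_radii
  co <- array(0, c(n_frames, n_sites, 3))
  centre <- c(0, 0, 0)
  Rm <- diag(3)
  for (t in seq_len(n_frames)) {
    if (t > 1) {
      centre <- centre + stats::rnorm(3, 0, sqrt(2 * D_t * dt))
      Rm <- rotation_matrix(stats::rnorm(3, 0, sqrt(2 * D_r * dt))) %*% Rm
    }
    co[t, , ] <- sweep(sites %*% t(Rm), 2, centre, `+`)
  }
  box <- max(1e6, 100 * max(site_radii, 1))
  trajectory(times = (seq_len(n_frames) - 1) * dt, coords = co,
             box = rep(box, 3), chain_id = rep(1L, n_sites),
             charge = rep(0, n_sites), mass = rep(1, n_sites),
             wrapped = FALSE,
             meta = list(D_t = D_t, D_r = D_r, site_radii = site_radii,
                         seed = seed))
}

#' Generate Ornstein-Uhlenbeck pressure series
#'
#' Independent stationary OU components with stationary standard
#' deviation \code{sigma} (bar) and correlation time \code{tau_c} (ns),
#' simulated with the exact discretisation. The implied Green-Kubo
#' viscosity V*sigma^2*tau_c/(kB*T) is recorded in the attributes.
#'
#' @param sigma bar.
#' @param tau_c ns.
#' @param dt ns (must resolve tau_c: dt < tau_c/5).
#' @param n_steps series length.
#' @param n_components number of tensor components.
#' @param seed RNG seed.
#' @param T,V temperature (K) and volume (Angstrom^3) used for the implied
#'   viscosity metadata.
#' @return data.frame with \code{time} and component columns; attribute
#'   \code{eta_true} in mPa*s.
#' @export
gen_ou_pressure <- function(sigma, tau_c, dt, n_steps, n_components = 5L,
                            seed = 1L, T = 300, V = 170^3) {
  stopifnot(sigma >= 0, tau_c > 0, dt > 0, n_steps > 1)
  if (dt >= tau_c / 5)
    stop("discretisation error: dt must be below tau_c/5")
  set.seed(seed)
  a <- exp(-dt / tau_c)
  s_step <- sigma * sqrt(1 - a^2)
  out <- data.frame(time = (seq_len(n_steps) - 1) * dt)
  for (k in seq_len(n_components)) {
    x <- numeric(n_steps)
    x[1] <- stats::rnorm(1, 0, sigma)
    innov <- stats::rnorm(n_steps - 1, 0, s_step)
    for (t in 2:n_steps) x[t] <- a * x[t - 1] + innov[t - 1]
    out[[paste0("P", k)]] <- x
  }
  attr(out, "eta_true") <- 1e-26 * V * sigma^2 * tau_c / (pt_constants$kB_SI * T)
  attr(out, "truth") <- list(sigma = sigma, tau_c = tau_c, seed = seed,
                             T = T, V = V)
  out
}

#' Generate a logistic proteome stability curve
#'
#' r_u(T) = plateau / (1 + exp(-steepness*(T - midpoint))), with
#' a_u = r_u^p for the configured power-law map. The published bound that
#' fewer than a quarter of the proteins unfold just above the cell-death
#' temperature motivates the default plateau of 0.25.
#'
#' @param midpoint K.
#' @param steepness 1/K.
#' @param plateau asymptotic unfolded fraction in [0, 1].
#' @param T_grid temperatures, K.
#' @param map a \code{power_law_map}.
#' @return a \code{stability_curve} data.frame (T, a_u, r_u, f) with the
#'   truth parameters in attribute \code{truth}.
#' @export
gen_stability_curve <- function(midpoint = 330, steepness = 0.2,
                                plateau = 0.25,
                                T_grid = seq(275, 362, by = 1),
                                map = power_law_map("a99SB-disp")) {
  if (plateau < 0 || plateau > 1)
    stop("invalid parameter: plateau must lie in [0, 1]")
  r_u <- plateau / (1 + exp(-steepness * (T_grid - midpoint)))
  a_u <- r_u^map$p
  out <- data.frame(T = T_grid, a_u = a_u, r_u = r_u, f = 1 - r_u,
                    r_u_se = NA_real_)
  class(out) <- c("stability_curve", class(out))
  attr(out, "truth") <- list(midpoint = midpoint, steepness = steepness,
                             plateau = plateau, p = map$p)
  out
}

#' Generate noisy growth-rate data from the kinetic model
#'
#' @param params a \code{growth_params} (truth).
#' @param stability a \code{stability_curve} covering \code{T_range}.
#' @param D_G_series optional (T, D_G) data.frame for the diffusive modes.
#' @param noise_rel relative Gaussian noise.
#' @param n_points number of temperatures.
#' @param T_range c(min, max), K.
#' @param seed RNG seed.
#' @return a data.frame (T, g, g_se) with truth in attribute \code{truth}.
#' @export
gen_growth_data <- function(params, stability, D_G_series = NULL,
                            noise_rel = 0.03, n_points = 30,
                            T_range = c(280, 326), seed = 1L) {
  if (T_range[1] < min(stability$T) || T_range[2] > max(stability$T))
    stop("range error: T_range outside the stability curve")
  Tn <- seq(T_range[1], T_range[2], length.out = n_points)
  f <- interp_curve(stability$T, stability$f, Tn)
  Dg <- if (!is.null(D_G_series))
    interp_curve(D_G_series$T, D_G_series$D_G, Tn) else NULL
  g <- growth_rate(Tn, params, f, Dg)
  g_true <- g
  if (noise_rel > 0) {
    set.seed(seed)
    g <- g * (1 + noise_rel * stats::rnorm(n_points))
    g[g < 0] <- 0
  }
  # floor the uncertainty relative to the data scale so weighting stays
  # invariant under a rescaling of g0
  out <- data.frame(T = Tn, g = g,
                    g_se = pmax(noise_rel * g_true, 1e-12 * max(g_true)))
  attr(out, "truth") <- list(params = params, noise_rel = noise_rel,
                             seed = seed, g_true = g_true)
  out
}
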