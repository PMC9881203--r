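#' Fit configuration
#'
#' @param strategy "two_stage" (per-q Lorentzian fits, then jump-diffusion
#'   and EISF fits across q) or "global" (all q slices simultaneously with
#'   shared dynamical parameters).
#' @param bounds named list of c(lower, upper) overriding the defaults
#'   D in [0, 100] Angstrom^2/ns, tau_G in [0, 10] ns, tau_L in [0, 2000] ps,
#'   r_L in [0.1, 10] Angstrom, p_L in [0, 1].
#' @param init named list of initial values (optional; data-driven
#'   heuristics otherwise).
#' @param max_iter maximum optimiser iterations.
#' @param weight_mode "inverse_variance" or "uniform".
#' @param include_solvent fit a solvent Lorentzian term (global strategy
#'   exposes its weight phi as a parameter).
#' @param gamma_D2O per-q solvent hwhm table, micro-eV (recycled).
#' @param db_mode detailed-balance convention used in the model.
#' @param n_starts seeded multi-start attempts on non-convergence.
#' @param random_seed seed for multi-start jitter.
#' @export
fit_config <- function(strategy = c("two_stage", "global"),
                       bounds = list(), init = list(), max_iter = 200L,
                       weight_mode = c("inverse_variance", "uniform"),
                       include_solvent = FALSE, gamma_D2O = 1,
                       db_mode = "symmetric", n_starts = 5L,
                       random_seed = 1L) {
  strategy <- match.arg(strategy)
  weight_mode <- match.arg(weight_mode)
  if (max_iter <= 0) stop("max_iter must be > 0")
  b <- list(D_G = c(0, 100), tau_G = c(0, 10), D_L = c(0, 100),
            tau_L = c(0, 2000), r_L = c(0.1, 10), p_L = c(0, 1),
            phi = c(0, 1))
  for (nm in names(bounds)) {
    if (bounds[[nm]][1] > bounds[[nm]][2]) stop("bounds lower > upper for ", nm)
    b[[nm]] <- bounds[[nm]]
  }
  structure(list(strategy = strategy, bounds = b, init = init,
                 max_iter = as.integer(max_iter), weight_mode = weight_mode,
                 include_solvent = include_solvent, gamma_D2O = gamma_D2O,
                 db_mode = db_mode, n_starts = as.integer(n_starts),
                 random_seed = as.integer(random_seed)),
            class = "fit_config")
}

lm_ctrl <- function(cfg)
  minpack.lm::nls.lm.control(maxiter = cfg$max_iter,
                             maxfev = 100L * cfg$max_iter)

# standard errors from the Gauss-Newton curvature of a converged nls.lm fit
lm_se <- function(fit, n_obs) {
  np <- length(fit$par)
  dof <- max(n_obs - np, 1L)
  s2 <- fit$deviance / dof
  cov <- try(solve(fit$hessian) * s2, silent = TRUE)
  if (inherits(cov, "try-error"))
    return(stats::setNames(rep(NA_real_, np), names(fit$par)))
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- names(fit$par)
  se
}

#' Fit the jump-diffusion model to q-resolved widths
#'
#' Weighted least-squares fit of hwhm(q) = hbar*D*q^2/(1 + D*q^2*tau).
#'
#' @param q_values 1/Angstrom (>= 3 points).
#' @param widths hwhm, micro-eV (> 0).
#' @param width_errors standard errors on the widths (optional).
#' @return list with D (Angstrom^2/ns), tau (ns), D_se, tau_se, converged.
#' @export
fit_jump_diffusion <- function(q_values, widths, width_errors = NULL) {
  if (length(q_values) < 3L)
    stop("insufficient data: at least 3 q points required")
  if (any(widths <= 0)) stop("widths must be > 0")
  w <- if (is.null(width_errors)) rep(1, length(widths)) else 1 / width_errors
  if (any(!is.finite(w))) {
    fin <- w[is.finite(w)]
    w[!is.finite(w)] <- if (length(fin)) stats::median(fin) else 1
    if (!length(fin)) w[] <- 1
  }
  hbar <- pt_constants$hbar_ueV_ns
  # init: Fickian fit to the two lowest q, plateau from the highest width
  o <- order(q_values)
  D0 <- mean(widths[o[1:2]] / (hbar * q_values[o[1:2]]^2))
  tau0 <- max(hbar / max(widths) - 1 / (D0 * max(q_values)^2), 0)
  resid_fn <- function(p) {
    (widths - hbar * p[1] * q_values^2 / (1 + p[1] * q_values^2 * p[2])) * w
  }
  fit <- minpack.lm::nls.lm(par = c(D = max(D0, 1e-3), tau = tau0),
                            lower = c(0, 0), upper = c(100, 10),
                            fn = resid_fn)
  se <- lm_se(fit, length(widths))
  list(D = unname(fit$par["D"]), tau = unname(fit$par["tau"]),
       D_se = unname(se["D"]), tau_se = unname(se["tau"]),
       converged = fit$info %in% 1:4)
}

# ---- per-q slice fit (stage 1 of the two-stage strategy) ---------------

fit_q_slice <- function(E, S, dS, kern, dE, db, init, cfg, gamma_D2O_q = 1) {
  w <- if (cfg$weight_mode == "inverse_variance") 1 / dS else rep(1, length(S))
  half_range <- max(abs(E))
  slice_model <- function(p) {
    shape <- p["I"] * (p["A0"] * lorentzian(E, p["gG"]) +
                       (1 - p["A0"]) * lorentzian(E, p["gG"] + p["gL"]))
    if (cfg$include_solvent)
      shape <- shape + p["s"] * lorentzian(E, gamma_D2O_q)
    db * convolve_uniform(shape, kern, dE)
  }
  lower <- c(I = 0, A0 = 0, gG = 1e-5, gL = 1e-4)
  upper <- c(I = Inf, A0 = 1, gG = half_range, gL = 2 * half_range)
  if (cfg$include_solvent) {
    lower <- c(lower, s = 0); upper <- c(upper, s = Inf)
  }
  init <- init[names(lower)]
  fit <- minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                            fn = function(p) (S - slice_model(p)) * w,
                            control = lm_ctrl(cfg))
  se <- lm_se(fit, length(S))
  dof <- max(length(S) - length(init), 1L)
  list(par = fit$par, se = se, redchi2 = fit$deviance / dof,
       converged = fit$info %in% 1:4)
}

#' Fit the scattering model to one spectrum
#'
#' Two-stage strategy: (1) per-q fit of the resolution-convolved
#' two-Lorentzian (plus optional solvent) model for widths and amplitudes,
#' warm-starting each q from its neighbour; (2) jump-diffusion fits of
#' gamma_G(q) and gamma_L(q); (3) EISF fit of A0(q) for (r_L, p_L).
#' Global strategy: simultaneous fit of all q slices with shared
#' (D_G, tau_G, D_L, tau_L, r_L, p_L) and free per-q intensities.
#'
#' @param spectrum a \code{qens_spectrum}.
#' @param resolution a \code{resolution_model}.
#' @param config a \code{fit_config}.
#' @return a \code{fit_result}: fitted \code{spectrum_params}, standard
#'   errors, reduced chi-square, convergence flag, per-q diagnostics.
#' @export
fit_spectrum <- function(spectrum, resolution, config = fit_config()) {
  stopifnot(inherits(spectrum, "qens_spectrum"))
  if (any(spectrum$uncertainties == 0))
    stop("weighting error: uncertainties must be non-zero")
  # normalise the overall count scale before fitting: the optimiser's
  # termination and restart decisions must not depend on detector calibration
  sc <- mean(abs(spectrum$intensities))
  if (!is.finite(sc) || sc <= 0) sc <- 1
  spectrum$intensities <- spectrum$intensities / sc
  spectrum$uncertainties <- spectrum$uncertainties / sc
  if (!is.null(config$init$intensity))
    config$init$intensity <- config$init$intensity / sc
  if (!is.null(config$init$solvent_amplitude))
    config$init$solvent_amplitude <- config$init$solvent_amplitude / sc
  fit <- if (config$strategy == "two_stage")
    fit_spectrum_two_stage(spectrum, resolution, config)
  else
    fit_spectrum_global(spectrum, resolution, config)
  fit$params$intensity <- fit$params$intensity * sc
  fit$params$solvent_amplitude <- fit$params$solvent_amplitude * sc
  if (!is.null(fit$per_q)) fit$per_q$I <- fit$per_q$I * sc
  fit
}

fit_spectrum_two_stage <- function(spectrum, resolution, cfg) {
  E <- spectrum$energy_grid
  dE <- check_uniform_grid(E)
  q <- spectrum$q_values
  nq <- length(q)
  db <- detailed_balance(E, spectrum$temperature, cfg$db_mode)
  gD2O <- rep_len(cfg$gamma_D2O, nq)
  per_q <- vector("list", nq)
  init <- c(I = NA, A0 = 0.7, gG = NA, gL = 2,
            if (cfg$include_solvent) c(s = 0))
  ok <- TRUE
  for (i in seq_len(nq)) {
    kern <- resolution_kernel(resolution, E, i)
    if (i == 1L || !per_q[[i - 1L]]$converged) {
      init["I"] <- sum(spectrum$intensities[i, ]) * dE
      init["gG"] <- pmin(pmax(pt_constants$hbar_ueV_ns * 1.0 * q[i]^2, 1e-3),
                         max(abs(E)) / 2)
    } else {
      prev <- per_q[[i - 1L]]$par
      init[names(prev)] <- prev
      init["gG"] <- prev["gG"] * (q[i] / q[i - 1L])^2
      init["I"] <- sum(spectrum$intensities[i, ]) * dE
    }
    res <- fit_q_slice(E, spectrum$intensities[i, ], spectrum$uncertainties[i, ],
                       kern, dE, db, init, cfg, gD2O[i])
    # restart on non-convergence, poor fit quality, or a degenerate solution
    # with the quasi-elastic fraction pinned at zero (A0 at its bound)
    if (!res$converged || res$redchi2 > 1.5 || res$par[["A0"]] > 0.995) {
      set.seed(cfg$random_seed + i)
      for (k in seq_len(cfg$n_starts)) {
        jit <- init * exp(stats::rnorm(length(init), 0, 0.3))
        jit["A0"] <- stats::runif(1, 0.2, 0.9)
        jit["gL"] <- exp(stats::runif(1, log(0.5), log(10)))
        res2 <- fit_q_slice(E, spectrum$intensities[i, ],
                            spectrum$uncertainties[i, ], kern, dE, db,
                            jit, cfg, gD2O[i])
        # a converged candidate also wins over an unconverged incumbent that
        # it matches in deviance (the incumbent merely ran out of iterations)
        if (res2$converged &&
            (res2$redchi2 < res$redchi2 ||
             (!res$converged && res2$redchi2 <= res$redchi2 * 1.001)))
          res <- res2
        if (res$converged && res$redchi2 <= 1.5) break
      }
    }
    ok <- ok && res$converged
    per_q[[i]] <- res
  }
  pq <- do.call(rbind, lapply(seq_len(nq), function(i) {
    p <- per_q[[i]]$par; s <- per_q[[i]]$se
    data.frame(q = q[i], I = p[["I"]], A0 = p[["A0"]],
               gamma_G = p[["gG"]], gamma_L = p[["gL"]],
               gamma_G_se = s[["gG"]], gamma_L_se = s[["gL"]],
               A0_se = s[["A0"]], redchi2 = per_q[[i]]$redchi2)
  }))
  jdG <- fit_jump_diffusion(q, pq$gamma_G, pq$gamma_G_se)
  jdL <- fit_jump_diffusion(q, pq$gamma_L, pq$gamma_L_se)
  ef <- fit_eisf(q, pq$A0, pq$A0_se)
  params <- spectrum_params(intensity = pq$I, D_G = jdG$D, tau_G = jdG$tau,
                            D_L = jdL$D, tau_L = jdL$tau * 1000,
                            r_L = ef$r_L, p_L = ef$p_L)
  se <- c(D_G = jdG$D_se, tau_G = jdG$tau_se, D_L = jdL$D_se,
          tau_L = jdL$tau_se * 1000, r_L = ef$r_L_se, p_L = ef$p_L_se)
  structure(list(params = params, se = se,
                 redchi2 = mean(pq$redchi2),
                 converged = ok && jdG$converged && jdL$converged,
                 per_q = pq, strategy = "two_stage"),
            class = "fit_result")
}

fit_eisf <- function(q_values, A0, A0_se = NULL) {
  w <- if (is.null(A0_se)) rep(1, length(A0)) else 1 / pmax(A0_se, 1e-6)
  w[!is.finite(w)] <- 1
  A0c <- pmin(pmax(A0, 0), 1)
  fit <- minpack.lm::nls.lm(par = c(r_L = 2, p_L = max(min(A0c), 1e-3)),
                            lower = c(0.1, 0), upper = c(10, 1),
                            fn = function(p) (A0c - eisf(q_values, p[1], p[2])) * w)
  se <- lm_se(fit, length(A0))
  list(r_L = unname(fit$par["r_L"]), p_L = unname(fit$par["p_L"]),
       r_L_se = unname(se["r_L"]), p_L_se = unname(se["p_L"]),
       converged = fit$info %in% 1:4)
}

fit_spectrum_global <- function(spectrum, resolution, cfg) {
  E <- spectrum$energy_grid
  dE <- check_uniform_grid(E)
  q <- spectrum$q_values
  nq <- length(q)
  db <- detailed_balance(E, spectrum$temperature, cfg$db_mode)
  kerns <- lapply(seq_len(nq), function(i) resolution_kernel(resolution, E, i))
  gD2O <- rep_len(cfg$gamma_D2O, nq)
  w <- if (cfg$weight_mode == "inverse_variance")
    1 / spectrum$uncertainties else array(1, dim(spectrum$intensities))

  # warm-start dynamical parameters from a quick two-stage pass unless given
  init <- cfg$init
  if (is.null(init$D_G)) {
    ts <- try(fit_spectrum_two_stage(spectrum, resolution, cfg), silent = TRUE)
    if (!inherits(ts, "try-error")) {
      p <- ts$params
      init <- utils::modifyList(list(D_G = p$D_G, tau_G = p$tau_G, D_L = p$D_L,
                                     tau_L = p$tau_L, r_L = p$r_L, p_L = p$p_L,
                                     intensity = p$intensity), init)
    } else {
      init <- utils::modifyList(list(D_G = 1, tau_G = 0.1, D_L = 20,
                                     tau_L = 150, r_L = 2, p_L = 0.5,
                                     intensity = rowSums(spectrum$intensities) * dE),
                                init)
    }
  }
  if (is.null(init$intensity)) init$intensity <- rowSums(spectrum$intensities) * dE
  pvec <- c(init$D_G, init$tau_G, init$D_L, init$tau_L, init$r_L, init$p_L,
            if (cfg$include_solvent) if (is.null(init$phi)) 0.1 else init$phi,
            rep_len(init$intensity, nq),
            if (cfg$include_solvent) rep_len(init$solvent_amplitude %||%
                                             (0.05 * init$intensity), nq))
  b <- cfg$bounds
  lower <- c(b$D_G[1], b$tau_G[1], b$D_L[1], b$tau_L[1], b$r_L[1], b$p_L[1],
             if (cfg$include_solvent) b$phi[1],
             rep(0, nq), if (cfg$include_solvent) rep(0, nq))
  upper <- c(b$D_G[2], b$tau_G[2], b$D_L[2], b$tau_L[2], b$r_L[2], b$p_L[2],
             if (cfg$include_solvent) b$phi[2],
             rep(Inf, nq), if (cfg$include_solvent) rep(Inf, nq))
  ns <- if (cfg$include_solvent) 1L else 0L
  resid_fn <- function(p) {
    A0 <- eisf(q, p[5], p[6])
    gG <- jump_diffusion_width(q, p[1], p[2])
    gL <- jump_diffusion_width(q, p[3], p[4] / 1000)
    I_q <- p[(6 + ns + 1):(6 + ns + nq)]
    amp <- if (ns) p[(6 + ns + nq + 1):(6 + ns + 2 * nq)] else rep(0, nq)
    phi <- if (ns) p[7] else 0
    r <- matrix(0, nq, length(E))
    for (i in seq_len(nq)) {
      shape <- I_q[i] * (A0[i] * lorentzian(E, gG[i]) +
                         (1 - A0[i]) * lorentzian(E, gG[i] + gL[i]))
      if (ns) shape <- shape + phi * amp[i] * lorentzian(E, gD2O[i])
      r[i, ] <- spectrum$intensities[i, ] - db * convolve_uniform(shape, kerns[[i]], dE)
    }
    as.vector(r * w)
  }
  fit <- minpack.lm::nls.lm(par = pvec, lower = lower, upper = upper,
                            fn = resid_fn, control = lm_ctrl(cfg))
  se_all <- lm_se(fit, length(spectrum$intensities))
  p <- fit$par
  params <- spectrum_params(intensity = p[(6 + ns + 1):(6 + ns + nq)],
                            D_G = p[1], tau_G = p[2], D_L = p[3],
                            tau_L = p[4], r_L = p[5], p_L = p[6],
                            phi = if (ns) p[7] else 0,
                            solvent_amplitude = if (ns)
                              p[(6 + ns + nq + 1):(6 + ns + 2 * nq)] else 0,
                            gamma_D2O = gD2O)
  se <- c(D_G = se_all[1], tau_G = se_all[2], D_L = se_all[3],
          tau_L = se_all[4], r_L = se_all[5], p_L = se_all[6],
          phi = if (ns) se_all[7] else NA_real_)
  dof <- max(length(spectrum$intensities) - length(pvec), 1L)
  structure(list(params = params, se = se, redchi2 = fit$deviance / dof,
                 converged = fit$info %in% 1:4, per_q = NULL,
                 strategy = "global"),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a temperature series of spectra
#'
#' Runs [fit_spectrum()] per temperature, warm-starting each fit from the
#' previous temperature's result, and assembles the Fig-1-style dynamics
#' series. A failing temperature is flagged, not fatal.
#'
#' @param spectra list of \code{qens_spectrum} (>= 2 temperatures).
#' @param resolution a \code{resolution_model}.
#' @param config a \code{fit_config}.
#' @param direction "heating" or "cooling" flags, recycled.
#' @return a \code{dynamics_series} data.frame with one row per temperature:
#'   T, D_G, tau_G, D_L, tau_L, r_L, p_L, their standard errors,
#'   \code{converged}, and \code{direction}.
#' @export
fit_temperature_series <- function(spectra, resolution, config = fit_config(),
                                   direction = "heating") {
  if (length(spectra) < 2L)
    stop("insufficient data: at least 2 temperatures required")
  direction <- rep_len(direction, length(spectra))
  rows <- vector("list", length(spectra))
  cfg <- config
  for (i in seq_along(spectra)) {
    fr <- try(fit_spectrum(spectra[[i]], resolution, cfg), silent = TRUE)
    if (inherits(fr, "try-error")) {
      rows[[i]] <- data.frame(T = spectra[[i]]$temperature, D_G = NA, tau_G = NA,
                              D_L = NA, tau_L = NA, r_L = NA, p_L = NA,
                              D_G_se = NA, tau_G_se = NA, D_L_se = NA,
                              tau_L_se = NA, r_L_se = NA, p_L_se = NA,
                              converged = FALSE, direction = direction[i])
      next
    }
    p <- fr$params; s <- fr$se
    rows[[i]] <- data.frame(T = spectra[[i]]$temperature,
                            D_G = p$D_G, tau_G = p$tau_G, D_L = p$D_L,
                            tau_L = p$tau_L, r_L = p$r_L, p_L = p$p_L,
                            D_G_se = s[["D_G"]], tau_G_se = s[["tau_G"]],
                            D_L_se = s[["D_L"]], tau_L_se = s[["tau_L"]],
                            r_L_se = s[["r_L"]], p_L_se = s[["p_L"]],
                            converged = fr$converged, direction = direction[i])
    if (fr$converged && config$strategy == "global")
      cfg$init <- list(D_G = p$D_G, tau_G = p$tau_G, D_L = p$D_L,
                       tau_L = p$tau_L, r_L = p$r_L, p_L = p$p_L)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dynamics_series", class(out))
  out
}
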