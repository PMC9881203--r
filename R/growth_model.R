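#' Growth-model parameter bundle
#'
#' The Arrhenius / reaction-diffusion growth-rate model
#' g(T) = G0(T) * exp(-deltaH/(R T)) * f(T)^Gamma, where f is the mean
#' folded fraction of the proteome and Gamma the number of essential
#' proteins. G0(T) is either the constant g0 ("constant_g0"), or
#' g0 * D_G(T) when the prefactor is diffusion-limited
#' ("diffusion_prefactor"); "no_barrier" keeps the diffusion prefactor and
#' fixes deltaH = 0.
#'
#' @param g0 intrinsic growth-rate parameter (> 0; absorbs the units of g).
#' @param deltaH dominant activation barrier, kJ/mol (>= 0).
#' @param Gamma number of essential proteins (>= 0; treated as continuous).
#' @param mode "constant_g0", "diffusion_prefactor" or "no_barrier".
#' @export
growth_params <- function(g0, deltaH, Gamma,
                          mode = c("constant_g0", "diffusion_prefactor",
                                   "no_barrier")) {
  mode <- match.arg(mode)
  if (mode == "no_barrier") deltaH <- 0
  if (!is.finite(g0) || g0 <= 0) stop("invalid parameter: g0 must be > 0")
  if (deltaH < 0 || Gamma < 0) stop("deltaH and Gamma must be >= 0")
  structure(list(g0 = g0, deltaH = deltaH, Gamma = Gamma, mode = mode),
            class = "growth_params")
}

#' Growth rate at temperature T
#'
#' @param T temperature, K.
#' @param params a \code{growth_params}.
#' @param folded_fraction f(T) in [0, 1] (vector matching T).
#' @param D_G apparent diffusion coefficient(s), Angstrom^2/ns; required in
#'   the diffusion_prefactor and no_barrier modes.
#' @return growth rate in the units g0 carries.
#' @export
growth_rate <- function(T, params, folded_fraction, D_G = NULL) {
  f <- folded_fraction
  if (any(f < 0 | f > 1)) stop("invalid parameter: folded_fraction outside [0, 1]")
  diffusive <- params$mode %in% c("diffusion_prefactor", "no_barrier")
  if (diffusive && is.null(D_G))
    stop("missing input: D_G is required in mode ", params$mode)
  G0 <- if (diffusive) params$g0 * D_G else params$g0
  arr <- if (params$mode == "no_barrier") 1
         else exp(-params$deltaH / (pt_constants$R_kJ_mol_K * T))
  G0 * arr * f^params$Gamma
}

interp_curve <- function(x, y, xout, what = "curve") {
  if (any(xout < min(x) - 1e-9) || any(xout > max(x) + 1e-9))
    stop("range error: data temperatures extend beyond the ", what, " range")
  stats::approx(x, y, xout, rule = 1)$y
}

#' Fit the growth-rate model to (T, g) data
#'
#' Weighted nonlinear least squares over (g0, deltaH, Gamma) — the subset
#' free in the chosen mode — with the folded fraction (and D_G, if used)
#' linearly interpolated from the supplied curves onto the data
#' temperatures. Because log g is linear in (log g0, deltaH, Gamma), a
#' log-space regression provides the starting point; multi-start over
#' seeded jitters guards the known deltaH-Gamma anti-correlation, best
#' chi-square wins with ties broken toward smaller Gamma.
#'
#' @param data data.frame with columns T, g and optionally g_se.
#' @param stability a \code{stability_curve} (supplies f(T) = 1 - r_u).
#' @param D_G_series optional data.frame with columns T, D_G.
#' @param mode model variant, see [growth_params()].
#' @param n_starts seeded multi-start attempts.
#' @param seed RNG seed for the jitters.
#' @return list with \code{params} (a \code{growth_params}),
#'   \code{Gamma_rounded}, standard errors, residuals, reduced chi-square
#'   and convergence flag.
#' @export
fit_growth <- function(data, stability, D_G_series = NULL,
                       mode = c("constant_g0", "diffusion_prefactor",
                                "no_barrier"),
                       n_starts = 10L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(c("T", "g") %in% names(data)))
  if (any(data$g < 0)) stop("rates must be >= 0")
  f <- interp_curve(stability$T, stability$f, data$T, "stability curve")
  diffusive <- mode %in% c("diffusion_prefactor", "no_barrier")
  Dg <- NULL
  if (diffusive) {
    if (is.null(D_G_series)) stop("missing input: D_G series required in mode ", mode)
    Dg <- interp_curve(D_G_series$T, D_G_series$D_G, data$T, "D_G series")
  }
  w <- if (!is.null(data$g_se) && all(data$g_se > 0)) 1 / data$g_se
       else rep(1, nrow(data))
  R <- pt_constants$R_kJ_mol_K
  pos <- data$g > 0 & f > 0
  # log-space linear regression for the starting point
  y <- log(data$g[pos]) - if (diffusive) log(Dg[pos]) else 0
  X <- cbind(1, -1 / (R * data$T[pos]), log(f[pos]))
  est <- if (mode == "no_barrier") {
    cf0 <- stats::coef(stats::lm(y ~ X[, 3]))
    c(g0 = exp(unname(cf0[1])), deltaH = 0, Gamma = max(unname(cf0[2]), 0))
  } else {
    cf <- stats::coef(stats::lm(y ~ X[, 2] + X[, 3]))
    c(g0 = exp(unname(cf[1])), deltaH = max(unname(cf[2]), 0),
      Gamma = max(unname(cf[3]), 0))
  }
  free <- if (mode == "no_barrier") c("g0", "Gamma") else c("g0", "deltaH", "Gamma")
  model_g <- function(p) {
    pars <- growth_params(p[["g0"]],
                          if (mode == "no_barrier") 0 else p[["deltaH"]],
                          p[["Gamma"]], mode)
    growth_rate(data$T, pars, f, Dg)
  }
  run_fit <- function(p0) {
    minpack.lm::nls.lm(par = p0,
                       lower = rep(1e-12, length(p0)),
                       upper = unname(c(g0 = Inf, deltaH = 500,
                                        Gamma = 5000)[names(p0)]),
                       fn = function(p) (data$g - model_g(p)) * w,
                       control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  p0 <- est[free]
  p0["g0"] <- max(p0[["g0"]], 1e-10)
  best <- run_fit(p0)
  set.seed(seed)
  for (k in seq_len(n_starts)) {
    jit <- p0 * exp(stats::rnorm(length(p0), 0, 0.4))
    cand <- try(run_fit(jit), silent = TRUE)
    if (inherits(cand, "try-error")) next
    better <- cand$deviance < best$deviance * (1 - 1e-8) ||
      (abs(cand$deviance - best$deviance) <= 1e-8 * best$deviance &&
       cand$par[["Gamma"]] < best$par[["Gamma"]])
    if (better) best <- cand
  }
  p <- best$par
  params <- growth_params(p[["g0"]],
                          if (mode == "no_barrier") 0 else p[["deltaH"]],
                          p[["Gamma"]], mode)
  se <- lm_se(best, nrow(data))
  resid <- data$g - model_g(p)
  dof <- max(nrow(data) - length(p), 1L)
  list(params = params, Gamma_rounded = round(params$Gamma), se = se,
       residuals = resid, redchi2 = sum((resid * w)^2) / dof,
       converged = best$info %in% 1:4)
}
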