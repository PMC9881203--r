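#' Two-state diffusion mixing model
#'
#' Endmember diffusion coefficients of the fully folded and fully unfolded
#' proteome, each linear in temperature: D^f(T) = c_f + m_f*T and
#' D^u(T) = c_u + m_u*T. The measured apparent coefficient is the
#' a_u-weighted mix of the two.
#'
#' @param c_f,m_f folded intercept (Angstrom^2/ns) and slope
#'   (Angstrom^2/ns/K).
#' @param c_u,m_u unfolded intercept and slope.
#' @export
two_state_model <- function(c_f, m_f, c_u, m_u) {
  structure(list(c_f = c_f, m_f = m_f, c_u = c_u, m_u = m_u),
            class = "two_state_model")
}

#' Endmember lines of a two-state model
#' @param model a \code{two_state_model}.
#' @param T temperatures, K.
#' @return list with vectors \code{D_f} and \code{D_u}.
#' @export
endmember_D <- function(model, T) {
  list(D_f = model$c_f + model$m_f * T, D_u = model$c_u + model$m_u * T)
}

#' Apparent unfolded fraction from a measured diffusion coefficient
#'
#' Inverts the two-state mixing relation
#' D_G = (1 - a_u) D^f(T) + a_u D^u(T):
#' a_u = (D^f - D_G)/(D^f - D^u). Values of D_G outside the endmember
#' envelope (as noise can produce) are clamped to it with a warning.
#'
#' @param D_G apparent diffusion coefficient(s), Angstrom^2/ns.
#' @param T temperature(s), K.
#' @param model a \code{two_state_model}.
#' @return a_u in [0, 1].
#' @export
apparent_unfolded_fraction <- function(D_G, T, model) {
  e <- endmember_D(model, T)
  if (any(abs(e$D_f - e$D_u) < 1e-12))
    stop("degenerate model: D_f(T) equals D_u(T)")
  a <- (e$D_f - D_G) / (e$D_f - e$D_u)
  if (any(a < 0 | a > 1, na.rm = TRUE)) {
    warning("D_G outside the endmember envelope; a_u clamped to [0, 1]")
    a <- pmin(pmax(a, 0), 1)
  }
  a
}

#' Fit the two-state mixing model to a D_G(T) series
#'
#' Weighted nonlinear fit of
#' D_G(T) = (1 - a_u(T)) D^f(T) + a_u(T) D^u(T) with both endmembers
#' linear in T and a_u(T) parameterised by a smooth monotone sigmoid
#' (a fitting device for the endmember lines; the final a_u per
#' temperature is re-derived pointwise by [stability_curve()]).
#'
#' @param series a \code{dynamics_series} (or data.frame with columns
#'   T, D_G and optionally D_G_se).
#' @param fit_range optional c(Tmin, Tmax) restriction, K.
#' @param au_shape "logistic" (midpoint + steepness), "scaled_logistic"
#'   (adds a plateau amplitude in (0, 1]), or "power_logistic"
#'   (a_u = (scaled logistic)^p with the exponent taken from \code{map} —
#'   the natural device when the power-law map that will be applied
#'   downstream is already known, since then the sigmoid lives on the
#'   r_u scale).
#' @param map a \code{power_law_map}; required for "power_logistic".
#' @param constraints optional named list fixing parameters, e.g.
#'   list(m_u = 0).
#' @return list with \code{model} (a \code{two_state_model}), the sigmoid
#'   parameters, standard errors and convergence flag.
#' @export
fit_two_state <- function(series, fit_range = NULL,
                          au_shape = c("logistic", "scaled_logistic",
                                       "power_logistic"),
                          map = NULL, constraints = list()) {
  au_shape <- match.arg(au_shape)
  if (au_shape == "power_logistic" && is.null(map))
    stop("power_logistic shape requires a power_law_map")
  d <- as.data.frame(series)
  d <- d[is.finite(d$D_G), , drop = FALSE]
  if (!is.null(fit_range))
    d <- d[d$T >= fit_range[1] & d$T <= fit_range[2], , drop = FALSE]
  if (nrow(d) < 6L)
    stop("insufficient data: at least 6 temperatures required")
  w <- if (!is.null(d$D_G_se) && all(is.finite(d$D_G_se)) && all(d$D_G_se > 0))
    1 / d$D_G_se else rep(1, nrow(d))
  Tn <- d$T
  Tm0 <- stats::median(Tn)
  # endmember lines initialised from the coldest / hottest thirds
  cold <- Tn <= stats::quantile(Tn, 1 / 3)
  hot <- Tn >= stats::quantile(Tn, 2 / 3)
  lf <- stats::lm(D_G ~ T, data = d[cold, ])
  lu <- stats::lm(D_G ~ T, data = d[hot, ])
  p0 <- c(c_f = unname(stats::coef(lf)[1]), m_f = unname(stats::coef(lf)[2]),
          c_u = unname(stats::coef(lu)[1]), m_u = unname(stats::coef(lu)[2]),
          Tm = Tm0, k = 10 / diff(range(Tn)))
  if (au_shape != "logistic") p0 <- c(p0, A = 0.9)
  fixed <- names(constraints)
  free <- setdiff(names(p0), fixed)
  au_fun <- function(p, T) {
    a <- 1 / (1 + exp(-p[["k"]] * (T - p[["Tm"]])))
    if (au_shape == "scaled_logistic") a <- p[["A"]] * a
    if (au_shape == "power_logistic") a <- (p[["A"]] * a)^map$p
    a
  }
  model_fun <- function(p, T) {
    a <- au_fun(p, T)
    (1 - a) * (p[["c_f"]] + p[["m_f"]] * T) + a * (p[["c_u"]] + p[["m_u"]] * T)
  }
  resid_fn <- function(pf) {
    p <- p0
    p[free] <- pf
    p[fixed] <- unlist(constraints)
    (d$D_G - model_fun(p, Tn)) * w
  }
  lower <- c(c_f = -Inf, m_f = -Inf, c_u = -Inf, m_u = -Inf,
             Tm = min(Tn) - 50, k = 1e-3, A = 1e-3)[free]
  upper <- c(c_f = Inf, m_f = Inf, c_u = Inf, m_u = Inf,
             Tm = max(Tn) + 50, k = 10, A = 1)[free]
  fit <- minpack.lm::nls.lm(par = p0[free], lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  # seeded multi-start: the sigmoid midpoint/steepness surface is multimodal
  set.seed(7L)
  for (s in 1:8) {
    jit <- p0
    jit["Tm"] <- Tm0 + stats::runif(1, -1, 1) * diff(range(Tn)) / 4
    jit["k"] <- p0[["k"]] * exp(stats::rnorm(1, 0, 1))
    if ("A" %in% names(jit)) jit["A"] <- stats::runif(1, 0.4, 1)
    cand <- try(minpack.lm::nls.lm(par = jit[free], lower = lower,
                                   upper = upper, fn = resid_fn,
                                   control = minpack.lm::nls.lm.control(maxiter = 500)),
                silent = TRUE)
    if (!inherits(cand, "try-error") && cand$deviance < fit$deviance)
      fit <- cand
  }
  p <- p0
  p[free] <- fit$par
  p[fixed] <- unlist(constraints)
  mdl <- two_state_model(p[["c_f"]], p[["m_f"]], p[["c_u"]], p[["m_u"]])
  e <- endmember_D(mdl, range(Tn))
  if (!all(e$D_f > e$D_u))
    warning("fitted endmember lines cross inside the data range")
  if (max(au_fun(p, Tn)) < 0.5)
    warning("unfolded branch weakly identified: a_u stays below 0.5 in range")
  se <- lm_se(fit, nrow(d))
  list(model = mdl, sigmoid = p[setdiff(names(p), c("c_f", "m_f", "c_u", "m_u"))],
       se = se, converged = fit$info %in% 1:4,
       fitted = model_fun(p, Tn), T = Tn)
}

#' Power-law map between actual and apparent unfolded fractions
#'
#' a_u = r_u^p, calibrated from crowded-solution molecular simulations.
#' The exponent depends on the protein force field used for the
#' calibration; both published presets are available.
#'
#' @param p exponent > 0, or a preset name "a99SB-disp" (p = 0.411) /
#'   "CHARMM36m" (p = 0.142).
#' @export
power_law_map <- function(p = "a99SB-disp") {
  if (is.character(p)) {
    label <- p
    p <- switch(p, `a99SB-disp` = 0.411, CHARMM36m = 0.142,
                stop("unknown preset: ", p))
  } else label <- "custom"
  if (!is.finite(p) || p <= 0) stop("invalid parameter: p must be > 0")
  structure(list(p = p, force_field = label), class = "power_law_map")
}

#' Map apparent to actual unfolded fraction
#'
#' Inverts a_u = r_u^p: r_u = a_u^(1/p).
#'
#' @param a_u apparent unfolded fraction(s) in [0, 1].
#' @param map a \code{power_law_map}.
#' @export
map_au_to_ru <- function(a_u, map) {
  if (any(a_u < 0 | a_u > 1, na.rm = TRUE))
    stop("invalid parameter: a_u must lie in [0, 1]")
  a_u^(1 / map$p)
}

#' Fit the power-law exponent from paired (r_u, a_u) samples
#'
#' Zero-intercept least squares in log-log space:
#' log a_u = p * log r_u.
#'
#' @param r_u_samples,a_u_samples samples in (0, 1].
#' @return a \code{power_law_map} with attribute \code{p_se}.
#' @export
fit_power_law <- function(r_u_samples, a_u_samples) {
  if (length(r_u_samples) < 3L) stop("insufficient data: >= 3 pairs required")
  if (any(r_u_samples <= 0) || any(a_u_samples <= 0))
    stop("invalid parameter: samples must be in (0, 1]")
  x <- log(r_u_samples)
  y <- log(a_u_samples)
  keep <- is.finite(x) & is.finite(y) & x != 0
  fit <- stats::lm(y ~ x + 0, subset = keep)
  m <- power_law_map(unname(stats::coef(fit)[1]))
  attr(m, "p_se") <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit))))[1])
  m
}

#' Proteome stability curve from a dynamics series
#'
#' Rowwise composition: a_u from the two-state inversion of D_G(T), then
#' r_u = a_u^(1/p). The uncertainty on r_u is propagated from the D_G
#' standard error by the delta method.
#'
#' @param series a \code{dynamics_series}.
#' @param model a \code{two_state_model}.
#' @param map a \code{power_law_map}.
#' @return a \code{stability_curve} data.frame with columns
#'   T, a_u, r_u, f, r_u_se.
#' @export
stability_curve <- function(series, model, map) {
  d <- as.data.frame(series)
  a_u <- suppressWarnings(apparent_unfolded_fraction(d$D_G, d$T, model))
  r_u <- map_au_to_ru(a_u, map)
  e <- endmember_D(model, d$T)
  # delta method: dr/dD = dr/da * da/dD; da/dD = -1/(D_f - D_u)
  dr_da <- ifelse(a_u > 0, (1 / map$p) * a_u^(1 / map$p - 1), 0)
  se <- if (!is.null(d$D_G_se)) abs(dr_da / (e$D_f - e$D_u)) * d$D_G_se
        else rep(NA_real_, nrow(d))
  out <- data.frame(T = d$T, a_u = a_u, r_u = r_u, f = 1 - r_u, r_u_se = se)
  class(out) <- c("stability_curve", class(out))
  out
}
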