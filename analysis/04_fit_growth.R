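#!/usr/bin/env Rscript
# Stage 4: fit the reaction-diffusion growth model.
#
# Generates noisy growth-rate data from the kinetic truth
# (constant_g0: deltaH = 45 kJ/mol, Gamma = 86; diffusion_prefactor:
# 35 kJ/mol, 81) over 280-326 K using the truth stability curve, then
# refits both variants against the *inferred* stability curve from
# stage 3, plus the barrier-free control.
#
# Input:  results/stability.csv, results/truth_stability.csv,
#         results/series.csv
# Output: results/growth_fits.json

suppressPackageStartupMessages(library(proteothermal))

seed <- 1L
curve <- read.csv(file.path("results", "stability.csv"))
truth_curve <- read.csv(file.path("results", "truth_stability.csv"))
series <- read_series_csv(file.path("results", "series.csv"))

# growth data only make sense below the unfolding transition: keep the
# overlap of the published 280-326 K habitat range with the scan
T_range <- c(min(truth_curve$T), 326)

out <- list()

gd1 <- gen_growth_data(growth_params(2, 45, 86), truth_curve,
                       noise_rel = 0.03, T_range = T_range, seed = seed)
f1 <- fit_growth(gd1, curve, mode = "constant_g0")
out$constant_g0 <- list(deltaH = f1$params$deltaH, Gamma = f1$params$Gamma,
                        Gamma_rounded = f1$Gamma_rounded,
                        redchi2 = f1$redchi2)

Dg <- series[, c("T", "D_G")]
gd2 <- gen_growth_data(growth_params(0.5, 35, 81,
                                     mode = "diffusion_prefactor"),
                       truth_curve, D_G_series = Dg, noise_rel = 0.03,
                       T_range = T_range, seed = seed + 1L)
f2 <- fit_growth(gd2, curve, D_G_series = Dg, mode = "diffusion_prefactor")
out$diffusion_prefactor <- list(deltaH = f2$params$deltaH,
                                Gamma = f2$params$Gamma,
                                Gamma_rounded = f2$Gamma_rounded,
                                redchi2 = f2$redchi2)

f0 <- fit_growth(gd2, curve, D_G_series = Dg, mode = "no_barrier")
out$no_barrier <- list(Gamma = f0$params$Gamma, redchi2 = f0$redchi2,
                       redchi2_ratio_vs_barrier = f0$redchi2 / f2$redchi2)

jsonlite::write_json(out, file.path("results", "growth_fits.json"),
                     auto_unbox = TRUE, digits = NA)
str(out)
message("stage 4 done: results/growth_fits.json")
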