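#!/usr/bin/env Rscript
# Stage 1: simulate the temperature scan.
#
# Generates the study's logistic proteome stability curve and, from it,
# one synthetic backscattering spectrum per temperature (16 q values,
# |E| <= 31 ueV, 0.75 ueV resolution, 2% relative noise). The apparent
# diffusion coefficient at each temperature is the two-state mixture of
# the folded and unfolded endmember lines.
#
# Outputs: results/spectra/T*.csv, results/truth_stability.csv

suppressPackageStartupMessages(library(proteothermal))

seed <- 1L
out_dir <- "results"
spec_dir <- file.path(out_dir, "spectra")
dir.create(spec_dir, recursive = TRUE, showWarnings = FALSE)

map <- power_law_map("a99SB-disp")
# the scan reaches 280 K so the folded endmember line is observed
# directly (a_u < 0.01 below ~290 K) instead of extrapolated
truth_curve <- gen_stability_curve(midpoint = 330, steepness = 0.25,
                                   plateau = 1.0,
                                   T_grid = seq(280, 362, length.out = 24),
                                   map = map)
write.csv(as.data.frame(truth_curve),
          file.path(out_dir, "truth_stability.csv"), row.names = FALSE)

endmembers <- two_state_model(7.9, -0.02, 3.7, -0.01)
res <- resolution_model()

for (i in seq_len(nrow(truth_curve))) {
  Ti <- truth_curve$T[i]
  e <- endmember_D(endmembers, Ti)
  D_G <- (1 - truth_curve$a_u[i]) * e$D_f + truth_curve$a_u[i] * e$D_u
  sp <- gen_qens_spectrum(
    spectrum_params(intensity = 1, D_G = D_G, tau_G = 0.05, D_L = 30,
                    tau_L = 180, r_L = 2, p_L = 0.4),
    res, T = Ti, noise_rel = 0.02, seed = seed + i)
  f <- file.path(spec_dir, sprintf("T%07.2fK.csv", Ti))
  write_spectrum_csv(sp, f)
  message(sprintf("T = %.2f K: D_G(truth) = %.3f A^2/ns -> %s",
                  Ti, D_G, f))
}
message("stage 1 done: ", nrow(truth_curve), " spectra in ", spec_dir)
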