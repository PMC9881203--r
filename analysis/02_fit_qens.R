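#!/usr/bin/env Rscript
# Stage 2: fit the scattering model to every spectrum.
#
# Two-stage fit per temperature: per-q Lorentzian decompositions, then
# jump-diffusion and EISF fits across q, yielding the apparent global
# diffusion coefficient D_G(T) plus the local-motion parameters.
#
# Input:  results/spectra/*.csv   Output: results/series.csv

suppressPackageStartupMessages(library(proteothermal))

spec_dir <- file.path("results", "spectra")
files <- list.files(spec_dir, pattern = "\\.csv$", full.names = TRUE)
if (length(files) == 0) stop("no spectra found; run 01_simulate_spectra.R")

spectra <- lapply(files, read_spectrum_csv)
message("fitting ", length(spectra), " spectra ...")
series <- fit_temperature_series(spectra, resolution_model(), fit_config())
write_series_csv(series, file.path("results", "series.csv"))
print(series[, c("T", "D_G", "D_G_se", "tau_L", "p_L", "converged")],
      row.names = FALSE)
message("stage 2 done: results/series.csv")
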