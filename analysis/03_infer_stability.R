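#!/usr/bin/env Rscript
# Stage 3: infer the proteome stability curve.
#
# Fits the two-state mixing model to D_G(T) (power_logistic sigmoid
# device, exponent from the a99SB-disp power-law map), inverts each
# temperature to the apparent unfolded fraction a_u and maps it to the
# actual unfolded fraction r_u = a_u^(1/p).
#
# Input:  results/series.csv
# Output: results/stability.csv, results/two_state_fit.json

suppressPackageStartupMessages(library(proteothermal))

series <- read_series_csv(file.path("results", "series.csv"))
map <- power_law_map("a99SB-disp")
fit <- fit_two_state(series, au_shape = "power_logistic", map = map)
curve <- stability_curve(series, fit$model, map)

write.csv(as.data.frame(curve), file.path("results", "stability.csv"),
          row.names = FALSE)
jsonlite::write_json(list(model = unclass(fit$model),
                          sigmoid = as.list(fit$sigmoid),
                          converged = fit$converged),
                     file.path("results", "two_state_fit.json"),
                     auto_unbox = TRUE, digits = NA)
print(as.data.frame(curve), row.names = FALSE)
message("stage 3 done: results/stability.csv")
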