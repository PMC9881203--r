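# proteothermal

Inference chain from quasi-elastic neutron scattering (QENS) spectra of
living bacteria to a proteome stability curve and an Arrhenius
reaction–diffusion model of the growth rate, together with the
molecular-trajectory observables (diffusion, rotation, viscosity,
contacts, clusters) that calibrate the chain, and seeded synthetic-data
generators that make every stage testable against known ground truth.

## The science in one paragraph

In-cell QENS measures the apparent global diffusion coefficient
`D_G(T)` of the *average* protein. Because unfolded proteins diffuse
more slowly than folded ones in a crowded cytoplasm, `D_G(T)` across a
temperature scan encodes the thermal unfolding of the whole proteome:
modelling it as a two-state mixture of folded and unfolded endmember
lines yields an apparent unfolded fraction `a_u(T)`, and a
crowding-simulation-calibrated power law `a_u = r_u^p` converts it to
the actual unfolded fraction `r_u(T)` — the proteome stability curve.
Its complement `f = 1 − r_u` then enters a kinetic model of bacterial
growth, `g(T) = G0(T)·exp(−ΔH†/RT)·f^Γ`, whose fitted parameters are
the dominant activation enthalpy ΔH† and the number Γ of essential
proteins that must all be folded for the cell to grow.

## Package layout

- `R/` — the package: scattering model and fitting (`qens_model`,
  `qens_fit`), stability inference (`unfold_infer`), growth model
  (`growth_model`), trajectory observables (`traj_analysis`), seeded
  generators (`synthetic_data`), plain-file orchestration (`pipeline`),
  CSV/XYZ I/O.
- `analysis/` — numbered driver scripts reproducing the study chain
  into `results/` (see *Reproduction* below).
- `scripts/acceptance.R` — standalone quality-metric report.
- `tests/testthat/` — the test suite, including `test-acceptance.R`
  with one block per end-to-end property.
- `vignettes/proteome-stability-inference.Rmd` — model assumptions,
  conventions, numerical choices, and known identifiability limits.

## Worked example

Fit one synthetic spectrum (16 q values, |E| ≤ 31 μeV, 0.75 μeV
resolution, 2% noise) and recover the generation truth:

```r
library(proteothermal)

sp <- gen_qens_spectrum(
  spectrum_params(intensity = 1, D_G = 1.5, tau_G = 0.1, D_L = 30,
                  tau_L = 180, r_L = 2, p_L = 0.4),
  T = 300, noise_rel = 0.02, seed = 42)
fit <- fit_spectrum(sp, resolution_model(), fit_config())
round(unlist(fit$params[c("D_G", "tau_G", "D_L", "tau_L", "r_L", "p_L")]), 3)
#>     D_G   tau_G     D_L   tau_L     r_L     p_L
#>   1.490   0.099  28.796 180.318   2.036   0.406
```

Run the full chain — simulate a 24-temperature scan from a logistic
stability curve, fit every spectrum, infer the curve, fit the growth
model:

```r
rep <- run_pipeline(list(out_dir = "chain_demo", seed = 1))
stab <- read.csv("chain_demo/stability.csv")
round(tail(stab[, c("T", "a_u", "r_u", "f")], 4), 3)
#>          T   a_u   r_u     f
#> 21 351.304 1.000 0.999 0.001
#> 22 354.870 1.000 1.000 0.000
#> 23 358.435 1.000 1.000 0.000
#> 24 362.000 0.995 0.989 0.011
gp <- jsonlite::read_json("chain_demo/growth_params.json")
sprintf("deltaH = %.1f kJ/mol, Gamma = %d (truth: 45, 86)",
        gp$deltaH, gp$Gamma_rounded)
#> [1] "deltaH = 40.1 kJ/mol, Gamma = 103 (truth: 45, 86)"
```

The inferred `r_u(T)` tracks the generating curve within 0.05 at every
temperature. The growth parameters are noticeably noisier than the
curve itself: the `f^Γ` term amplifies percent-level stability-curve
errors, so a single run recovers ΔH† only to ±6 kJ/mol and Γ to ±15–20
even though the ensemble median across seeds is accurate. This
propagation limit is quantified in the vignette and asserted in the
test suite.

## Reproduction

The study chain is reproduced by the numbered drivers, which write
plain CSV/JSON files into `results/`:

```sh
Rscript analysis/01_simulate_spectra.R     # temperature scan of spectra
Rscript analysis/02_fit_qens.R             # D_G(T) series
Rscript analysis/03_infer_stability.R      # stability curve r_u(T)
Rscript analysis/04_fit_growth.R           # growth fits, all 3 modes
Rscript analysis/05_trajectory_observables.R
```

A standalone metrics report (parameter-recovery errors, oracle
agreement, end-to-end curve error) is produced by:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

All numbers in it are computed at run time from seeded synthetic data;
nothing is hard-coded.
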