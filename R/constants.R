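#' Physical constants and unit conventions
#'
#' Units are fixed across the package: energy transfer E in micro-eV,
#' momentum transfer q in 1/Angstrom, diffusion coefficients in
#' Angstrom^2/ns, global residence time tau_G in ns, local residence time
#' tau_L in ps, temperature in K, viscosity in mPa*s, pressure in bar,
#' volume in Angstrom^3.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{hbar_ueV_ns}{reduced Planck constant, 0.6582119 micro-eV*ns}
#'   \item{kB_ueV_K}{Boltzmann constant, 86.17333 micro-eV/K}
#'   \item{kB_SI}{Boltzmann constant, 1.380649e-23 J/K}
#'   \item{R_kJ_mol_K}{molar gas constant, 8.31446e-3 kJ/(mol*K)}
#'   \item{xi_cubic}{cubic-lattice hydrodynamic self-term, 2.837297}
#' }
#' @export
pt_constants <- list(
  hbar_ueV_ns = 0.6582119,
  kB_ueV_K    = 86.17333,
  kB_SI       = 1.380649e-23,
  R_kJ_mol_K  = 8.31446e-3,
  xi_cubic    = 2.837297
)
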