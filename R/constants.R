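#' Physical constants and unit conventions
#'
#' All quantities in ecsmc use a single internal unit system chosen to match
#' how results are reported in the molecular-simulation literature on aqueous
#' electrolytes: energies in kJ/mol, lengths in nm, charges in elementary
#' charge units (e), temperatures in K, and pressures in bar.
#'
#' `ecs_constants()` returns the conversion constants used package-wide.
#'
#' @return Named list with elements:
#'   \item{kB}{molar Boltzmann (gas) constant, kJ/(mol K)}
#'   \item{ke}{Coulomb constant e^2/(4 pi eps0) in kJ nm / (mol e^2)}
#'   \item{bar_to_kJ_mol_nm3}{1 bar expressed in kJ/(mol nm^3)}
#'   \item{NA_}{Avogadro constant, 1/mol}
#'   \item{amu_per_nm3_to_kg_m3}{converts (g/mol)/nm^3 to kg/m^3}
#' @export
#' @examples
#' ecs_constants()$kB * 298.15  # thermal energy at 298.15 K, kJ/mol
ecs_constants <- function() {
  list(
    kB = 8.31446261815324e-3,       # kJ/(mol K)
    ke = 138.935458,                # kJ nm/(mol e^2)
    bar_to_kJ_mol_nm3 = 0.0602214076,
    NA_ = 6.02214076e23,
    amu_per_nm3_to_kg_m3 = 1.66053906892
  )
}

# internal shorthands
.kB <- 8.31446261815324e-3
.ke <- 138.935458
.P_UNIT <- 0.0602214076      # bar -> kJ/(mol nm^3)
.MW_WATER <- 18.015          # g/mol

#' Thermal energy k_B T in kJ/mol
#' @param T temperature (K)
#' @return numeric, kJ/mol
#' @export
kBT <- function(T) {
  stopifnot(is.numeric(T), all(T > 0))
  .kB * T
}
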