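#' Elemental and molecular constants used throughout the pipeline
#'
#' Returns the fixed physical constants the physiology calculations rest on.
#' Two carbon/nitrogen molar masses are carried deliberately: the regime
#' boundary relation uses the integer masses 12 and 14 (the form in which the
#' Egli boundary quotient is conventionally written), while all other
#' elemental conversions use 12.011 and 14.007. The difference is below 0.1%
#' and both are exposed so either convention can be audited.
#'
#' @return A named list:
#' \describe{
#'   \item{mm_C, mm_N}{molar masses of C and N (g/mol), 12.011 / 14.007.}
#'   \item{mm_C_boundary, mm_N_boundary}{integer masses 12 / 14 used only in
#'     the dual-limitation boundary quotient.}
#'   \item{mm_NH4Cl}{molar mass of ammonium chloride, 53.49 g/mol.}
#'   \item{mm_decanoic_acid}{molar mass of decanoic acid, 172.26 g/mol.}
#'   \item{carbons_per_decanoate}{carbon atoms per decanoate molecule, 10.}
#'   \item{biomass_g_per_cmol}{grams of PHA-free biomass per C-mol, 27.}
#'   \item{molar_volume_gas}{molar volume of an ideal gas at 25 degC, 1 atm
#'     (24.45 l/mol), used for off-gas CO2 conversion.}
#' }
#' @export
#' @examples
#' elemental_constants()$biomass_g_per_cmol
elemental_constants <- function() {
  list(
    mm_C = 12.011,
    mm_N = 14.007,
    mm_C_boundary = 12,
    mm_N_boundary = 14,
    mm_NH4Cl = 53.49,
    mm_decanoic_acid = 172.26,
    carbons_per_decanoate = 10,
    biomass_g_per_cmol = 27,
    molar_volume_gas = 24.45
  )
}

#' PHA repeat-unit masses and carbon counts
#'
#' Monomer repeat units of the medium-chain-length polyester:
#' 3-hydroxyhexanoate (C6H10O2), 3-hydroxyoctanoate (C8H14O2) and
#' 3-hydroxydecanoate (C10H18O2) as incorporated in the polymer chain
#' (i.e. polymer repeat-unit masses, not methyl-ester masses).
#'
#' @return A data frame with columns `monomer`, `repeat_mass` (g/mol) and
#'   `n_carbon`.
#' @export
pha_repeat_units <- function() {
  data.frame(
    monomer = c("C6", "C8", "C10"),
    repeat_mass = c(114.14, 142.20, 170.25),
    n_carbon = c(6L, 8L, 10L),
    stringsAsFactors = FALSE
  )
}

# Nitrogen detection limit of the ammonium assay, g N / l.
N_DETECTION_LIMIT <- 1.9e-3

# internal: stop with a formatted message
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# internal: multiplicative lognormal noise with unit mean and a given
# relative standard deviation (so planted values are recovered unbiased).
rlnorm_rsd <- function(n, rsd) {
  if (rsd <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rsd^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
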