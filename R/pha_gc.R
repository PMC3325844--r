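#' GC peak table for PHA monomer quantification
#'
#' One methanolysis run: peak areas for the monomer methyl esters and the
#' 3-methylbenzoic acid internal standard (IS), plus the run metadata needed
#' for single-point internal-standard calibration.
#'
#' @param peaks data frame with columns `monomer` (one of C6, C8, C10, IS)
#'   and `area` (>= 0); exactly one IS row is required.
#' @param internal_standard_mass_mg mass of internal standard in the
#'   derivatized sample, mg.
#' @param sample_dry_mass_mg lyophilized sample mass, mg.
#' @param response_factors named multipliers per monomer (default 1:
#'   single-point calibration without per-analyte correction).
#' @return list of class `gc_peak_table`.
#' @export
gc_peak_table <- function(peaks, internal_standard_mass_mg, sample_dry_mass_mg,
                          response_factors = c(C6 = 1, C8 = 1, C10 = 1)) {
  if (!all(c("monomer", "area") %in% names(peaks)))
    stopf("peaks needs columns monomer, area")
  if (any(peaks$area < 0)) stopf("peak areas must be >= 0")
  if (sum(peaks$monomer == "IS") != 1)
    stopf("exactly one internal-standard (IS) peak is required")
  if (sample_dry_mass_mg <= 0) stopf("sample dry mass must be > 0")
  if (internal_standard_mass_mg <= 0) stopf("internal standard mass must be > 0")
  structure(list(peaks = peaks,
                 internal_standard_mass_mg = internal_standard_mass_mg,
                 sample_dry_mass_mg = sample_dry_mass_mg,
                 response_factors = response_factors),
            class = "gc_peak_table")
}

#' Monomer masses from internal-standard calibration
#'
#' mass_m = area_m / area_IS * m_IS * rf_m for each monomer peak.
#'
#' @param table a [gc_peak_table()].
#' @return named numeric vector of monomer masses, mg.
#' @export
#' @examples
#' tbl <- gc_peak_table(data.frame(monomer = c("C8", "IS"),
#'                                 area = c(2000, 1000)),
#'                      internal_standard_mass_mg = 0.5,
#'                      sample_dry_mass_mg = 8)
#' quantify_monomers(tbl)  # C8 = 1 mg
quantify_monomers <- function(table) {
  is_area <- table$peaks$area[table$peaks$monomer == "IS"]
  if (is_area <= 0) stopf("internal-standard peak area must be > 0")
  mono <- table$peaks[table$peaks$monomer != "IS", , drop = FALSE]
  rf <- table$response_factors[mono$monomer]
  rf[is.na(rf)] <- 1
  out <- mono$area / is_area * table$internal_standard_mass_mg * rf
  names(out) <- mono$monomer
  out
}

#' Monomer composition, PHA content and mean repeat-unit mass
#'
#' Converts monomer masses to moles of polymer repeat units, expresses the
#' composition in mol%, the PHA content as percent of the sample dry mass,
#' and the abundance-weighted mean repeat-unit mass.
#'
#' @param masses named numeric vector (C6/C8/C10), mg.
#' @param sample_dry_mass_mg sample dry mass, mg.
#' @return list of class `monomer_composition`: `molpercent`,
#'   `pha_content` (% CDW), `mean_repeat_mass` (g/mol).
#' @export
monomer_composition <- function(masses, sample_dry_mass_mg) {
  if (all(masses <= 0)) stopf("at least one monomer mass must be > 0")
  if (sample_dry_mass_mg <= 0) stopf("sample dry mass must be > 0")
  ru <- pha_repeat_units()
  rm <- stats::setNames(ru$repeat_mass, ru$monomer)[names(masses)]
  if (anyNA(rm)) stopf("unknown monomer: %s",
                       paste(names(masses)[is.na(rm)], collapse = ", "))
  mol <- masses / rm
  molpct <- 100 * mol / sum(mol)
  structure(list(
    molpercent = molpct,
    pha_content = 100 * sum(masses) / sample_dry_mass_mg,
    mean_repeat_mass = sum((mol / sum(mol)) * rm)
  ), class = "monomer_composition")
}

#' Composition object from a printed mol% breakdown
#'
#' Builds a `monomer_composition` directly from mol percentages (as printed
#' in a culture summary table); the PHA content is left NA since no sample
#' mass is involved.
#'
#' @param molpercent named numeric (C6/C8/C10) mol%, summing to 100 +- 0.5.
#' @return list of class `monomer_composition`.
#' @export
composition_from_molpercent <- function(molpercent) {
  s <- sum(molpercent)
  if (abs(s - 100) > 0.5) stopf("mol%% must sum to 100 +- 0.5 (got %.2f)", s)
  ru <- pha_repeat_units()
  rm <- stats::setNames(ru$repeat_mass, ru$monomer)[names(molpercent)]
  if (anyNA(rm)) stopf("unknown monomer in composition")
  frac <- molpercent / s
  structure(list(molpercent = 100 * frac, pha_content = NA_real_,
                 mean_repeat_mass = sum(frac * rm)),
            class = "monomer_composition")
}

#' Carbon content of a PHA pool
#'
#' (pha_mass / mean repeat mass) * mean carbons per repeat unit, in C-mol/l.
#'
#' @param comp a `monomer_composition`.
#' @param pha_mass_g_per_l PHA concentration, g/l.
#' @return PHA carbon, C-mol/l.
#' @export
#' @examples
#' comp <- composition_from_molpercent(c(C6 = 4.3, C8 = 40.2, C10 = 55.5))
#' pha_carbon(comp, 3.73)  # ~0.215 C-mol/l
pha_carbon <- function(comp, pha_mass_g_per_l) {
  ru <- pha_repeat_units()
  nc <- stats::setNames(ru$n_carbon, ru$monomer)[names(comp$molpercent)]
  frac <- comp$molpercent / sum(comp$molpercent)
  (pha_mass_g_per_l / comp$mean_repeat_mass) * sum(frac * nc)
}
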