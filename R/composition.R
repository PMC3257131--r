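#' Tissue composition of an idealized perfused heart
#'
#' The "idealized perfused heart" is a fixed composition convention used to
#' interconvert metabolite contents (per g dry weight), molar concentrations
#' (per L cell water) and whole-tissue reaction rates.  The defaults are the
#' rat-heart constants used throughout the package: 202.6 g dry weight per kg
#' wet mass, 134.6 mL mitochondrial matrix water and 394.4 mL extra-matrix
#' water per kg wet mass, 73 umol/g dwt total creatine, 135 umol/g dwt total
#' (high-energy + inorganic) phosphate and 25 umol/g dwt adenine nucleotides
#' (ATP + ADP).
#'
#' @param dry_mass_fraction g dry weight per kg wet mass.
#' @param matrix_water L mitochondrial matrix water per kg wet mass.
#' @param extra_matrix_water L extra-matrix water per kg wet mass.
#' @param total_creatine total creatine (Cr + PCr), umol per g dwt.
#' @param total_phosphate total phosphate groups in the energy network
#'   (3 per ATP, 2 per ADP, 1 per PCr and Pi), umol per g dwt.
#' @param total_adn total adenine nucleotides (ATP + ADP), umol per g dwt.
#' @return An object of class `heart_composition`.
#' @examples
#' comp <- heart_composition()
#' content_to_molar(25, comp) # ~9.57 mM
#' @export
heart_composition <- function(dry_mass_fraction = 202.6,
                              matrix_water = 0.1346,
                              extra_matrix_water = 0.3944,
                              total_creatine = 73,
                              total_phosphate = 135,
                              total_adn = 25) {
  comp <- list(
    dry_mass_fraction = dry_mass_fraction,
    matrix_water = matrix_water,
    extra_matrix_water = extra_matrix_water,
    total_creatine = total_creatine,
    total_phosphate = total_phosphate,
    total_adn = total_adn
  )
  vals <- unlist(comp)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid composition: all fields must be positive and finite")
  }
  if (matrix_water + extra_matrix_water > 1) {
    stop("invalid composition: total water cannot exceed 1 L per kg wet mass")
  }
  if (total_adn >= total_phosphate) {
    stop("invalid composition: total_adn must be < total_phosphate")
  }
  structure(comp, class = "heart_composition")
}

#' @export
print.heart_composition <- function(x, ...) {
  cat("Idealized perfused heart composition\n")
  cat(sprintf("  dry mass:          %.1f g dwt / kg wm\n", x$dry_mass_fraction))
  cat(sprintf("  matrix water:      %.4f L / kg wm\n", x$matrix_water))
  cat(sprintf("  extra-matrix water:%.4f L / kg wm\n", x$extra_matrix_water))
  cat(sprintf("  total creatine:    %.1f umol / g dwt\n", x$total_creatine))
  cat(sprintf("  total phosphate:   %.1f umol / g dwt\n", x$total_phosphate))
  cat(sprintf("  ATP + ADP:         %.1f umol / g dwt\n", x$total_adn))
  invisible(x)
}

#' Oxidative stoichiometry constants
#'
#' @param atp_per_o2 mol ATP synthesized per mol O2 consumed (P/O2 ratio);
#'   the conventional value for full oxidative phosphorylation is 6.0.
#' @return An object of class `stoichiometry`.
#' @export
stoichiometry <- function(atp_per_o2 = 6.0) {
  if (!is.finite(atp_per_o2) || atp_per_o2 <= 0) {
    stop("atp_per_o2 must be positive")
  }
  structure(list(atp_per_o2 = atp_per_o2), class = "stoichiometry")
}

#' Convert a tissue content to a molar concentration
#'
#' Converts a metabolite content in umol per g dry weight to an average
#' concentration in mmol per L of total cell water (matrix + extra-matrix).
#'
#' @param content umol per g dwt (non-negative).
#' @param comp a [heart_composition()].
#' @return concentration in mM.
#' @examples
#' content_to_molar(25, heart_composition()) # 9.57 mM
#' @export
content_to_molar <- function(content, comp = heart_composition()) {
  stopifnot(inherits(comp, "heart_composition"))
  if (any(content < 0)) stop("content must be >= 0")
  water <- comp$matrix_water + comp$extra_matrix_water
  if (water <= 0) stop("invalid composition: non-positive water volume")
  content * comp$dry_mass_fraction / 1000 / water
}

#' Convert a molar concentration back to a tissue content
#'
#' Inverse of [content_to_molar()].
#'
#' @param conc mM.
#' @param comp a [heart_composition()].
#' @return content in umol per g dwt.
#' @export
molar_to_content <- function(conc, comp = heart_composition()) {
  stopifnot(inherits(comp, "heart_composition"))
  if (any(conc < 0)) stop("conc must be >= 0")
  water <- comp$matrix_water + comp$extra_matrix_water
  conc * water * 1000 / comp$dry_mass_fraction
}

#' Recalculation coefficient between per-dry-mass conventions
#'
#' Converts metabolite data expressed per L cell water in one study to the
#' per-dry-mass convention of another, from the water/wet-mass ratio of the
#' source study and the protein contents assumed by the two studies.  With
#' 435.2 mL H2O/kg wm, 160 g protein/kg wm (source) and 155 g protein/kg wm
#' (target) the coefficient is 0.4216.
#'
#' @param water_per_wm mL water per kg wet mass in the source study.
#' @param protein_source g protein per kg wet mass assumed by the source.
#' @param protein_target g protein per kg wet mass assumed by the target.
#' @return dimensionless multiplicative coefficient.
#' @examples
#' recalc_coefficient(435.2, 160, 155) # 0.4216
#' @export
recalc_coefficient <- function(water_per_wm, protein_source, protein_target) {
  if (any(c(water_per_wm, protein_source, protein_target) <= 0)) {
    stop("all inputs must be positive")
  }
  (water_per_wm / 1000) * (protein_target / protein_source)
}

#' Convert an ATP synthesis rate to an oxygen consumption rate
#'
#' Converts a whole-tissue ATP turnover in mmol ATP s^-1 kg wet mass^-1 to
#' the oxygen uptake in umol O2 min^-1 g dry weight^-1 at the given ATP/O2
#' stoichiometry.  The maximal working-heart load of 3.52 mmol/s/kg wm maps
#' to ~174 umol O2/min/g dwt at ATP/O2 = 6.
#'
#' @param atp_rate mmol ATP s^-1 kg wm^-1 (non-negative).
#' @param stoich a [stoichiometry()].
#' @param comp a [heart_composition()].
#' @return VO2 in umol O2 min^-1 g dwt^-1.
#' @examples
#' atp_rate_to_vo2(3.52) # ~173.7
#' @export
atp_rate_to_vo2 <- function(atp_rate, stoich = stoichiometry(),
                            comp = heart_composition()) {
  stopifnot(inherits(stoich, "stoichiometry"), inherits(comp, "heart_composition"))
  if (any(atp_rate < 0)) stop("atp_rate must be >= 0")
  atp_rate * 1000 / stoich$atp_per_o2 * 60 / comp$dry_mass_fraction
}

#' Convert an oxygen consumption rate to an ATP synthesis rate
#'
#' Inverse of [atp_rate_to_vo2()].
#'
#' @param vo2 umol O2 min^-1 g dwt^-1.
#' @param stoich a [stoichiometry()].
#' @param comp a [heart_composition()].
#' @return ATP rate in mmol s^-1 kg wm^-1.
#' @export
vo2_to_atp_rate <- function(vo2, stoich = stoichiometry(),
                            comp = heart_composition()) {
  stopifnot(inherits(stoich, "stoichiometry"), inherits(comp, "heart_composition"))
  if (any(vo2 < 0)) stop("vo2 must be >= 0")
  vo2 * comp$dry_mass_fraction / 60 * stoich$atp_per_o2 / 1000
}

#' PCr/O2 ratio from relative MtCK and translocase rates
#'
#' Computes the moles of PCr produced per mole of O2 consumed from the MtCK
#' (PCr production) and ANT (ATP export) rates expressed as percent of their
#' common maximum, assuming the ATP-export rate tracks oxygen consumption at
#' the given ATP/O2 stoichiometry.
#'
#' @param mtck_rate_rel MtCK rate, % of maximum.
#' @param ant_rate_rel ANT rate, % of maximum (must be > 0).
#' @param stoich a [stoichiometry()].
#' @return dimensionless PCr/O2 ratio.
#' @examples
#' pcr_o2_from_rates(65.17, 38.22) # ~10.2
#' @export
pcr_o2_from_rates <- function(mtck_rate_rel, ant_rate_rel,
                              stoich = stoichiometry()) {
  stopifnot(inherits(stoich, "stoichiometry"))
  if (any(ant_rate_rel <= 0)) stop("undefined ratio: ant_rate_rel must be > 0")
  stoich$atp_per_o2 * mtck_rate_rel / ant_rate_rel
}
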