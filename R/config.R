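#' Geometry of the 1-D diffusion path
#'
#' The diffusion path of 1.3 um spans ten 0.1 um myofibrillar units, two
#' cytosolic units and one intermembrane-space (IMS) unit; the mitochondrial
#' outer membrane (MOM) is a zero-volume interface between the last cytosolic
#' unit and the IMS, and the matrix is a separate well-mixed pool reached only
#' through the inner-membrane carriers.  Extra-matrix water is shared between
#' the twelve diffusive units in proportion to their length, except for a
#' small fixed fraction assigned to the IMS.
#'
#' @param n_myofibril_units number of myofibrillar grid units.
#' @param unit_length length of one unit, um.
#' @param n_cytosol_units number of cytosolic grid units.
#' @param ims_water_fraction fraction of extra-matrix water assigned to the
#'   IMS unit.
#' @param comp a [heart_composition()] supplying the water spaces.
#' @return An object of class `grid_geometry` with per-unit volumes in
#'   L per kg wet mass.
#' @export
grid_geometry <- function(n_myofibril_units = 10, unit_length = 0.1,
                          n_cytosol_units = 2, ims_water_fraction = 0.05,
                          comp = heart_composition()) {
  stopifnot(n_myofibril_units >= 1, n_cytosol_units >= 1,
            unit_length > 0, ims_water_fraction > 0, ims_water_fraction < 1)
  n_diff <- n_myofibril_units + n_cytosol_units   # Fickian chain
  n_units <- n_diff + 1L                          # + IMS
  v_ims <- comp$extra_matrix_water * ims_water_fraction
  v_unit <- rep((comp$extra_matrix_water - v_ims) / n_diff, n_diff)
  structure(list(
    n_myofibril_units = as.integer(n_myofibril_units),
    n_cytosol_units = as.integer(n_cytosol_units),
    n_units = as.integer(n_units),
    unit_length = unit_length,
    total_path = n_units * unit_length,
    unit_volumes = c(v_unit, v_ims),
    matrix_volume = comp$matrix_water,
    ims_index = n_units
  ), class = "grid_geometry")
}

#' System configuration: topology and parameter switches
#'
#' A `system_config` captures the structural variants of the energy-transfer
#' system: whether creatine kinase is present, whether MtCK is functionally
#' coupled to the adenine nucleotide translocase through the local ATP
#' microcompartment, how strongly the mitochondrial outer membrane restricts
#' adenine-nucleotide diffusion, what fraction of total CK activity sits in
#' the mitochondrial compartment, and optional down-scalings of the metabolite
#' pools.
#'
#' @param ck_present logical; is any creatine kinase present.
#' @param coupling_enabled logical; MtCK-ANT microcompartment coupling.
#' @param mom_restriction_coeff dimensionless multiplier (0, 1] applied to the
#'   adenine-nucleotide permeability of the MOM: 0.007 severe, 0.1 weak,
#'   1.0 none.  Creatine, phosphocreatine and Pi are never restricted.
#' @param mom_ps_base baseline volume-normalized MOM permeability, s^-1
#'   (relative to IMS volume); chosen so that unrestricted exchange is
#'   non-limiting.
#' @param mtck_fraction fraction of total CK activity in the mitochondrial
#'   compartment (0.3125 default, 0.08 for the low-MtCK variants).
#' @param adn_cr_scale divisor on adenine-nucleotide and total-creatine pools.
#' @param pi_scale divisor on the inorganic-phosphate pool.
#' @return An object of class `system_config`.
#' @export
system_config <- function(ck_present = TRUE,
                          coupling_enabled = TRUE,
                          mom_restriction_coeff = 0.007,
                          mom_ps_base = 12000,
                          mtck_fraction = 0.3125,
                          adn_cr_scale = 1,
                          pi_scale = 1) {
  if (mom_restriction_coeff <= 0 || mom_restriction_coeff > 1) {
    stop("mom_restriction_coeff must be in (0, 1]")
  }
  if (mtck_fraction < 0 || mtck_fraction >= 1) {
    stop("mtck_fraction must be in [0, 1)")
  }
  if (adn_cr_scale < 1 || pi_scale < 1) stop("pool scales must be >= 1")
  if (mom_ps_base <= 0) stop("mom_ps_base must be positive")
  structure(list(
    ck_present = isTRUE(ck_present),
    coupling_enabled = isTRUE(coupling_enabled),
    mom_restriction_coeff = as.numeric(mom_restriction_coeff),
    mom_ps_base = as.numeric(mom_ps_base),
    mtck_fraction = if (isTRUE(ck_present)) as.numeric(mtck_fraction) else 0,
    adn_cr_scale = as.numeric(adn_cr_scale),
    pi_scale = as.numeric(pi_scale)
  ), class = "system_config")
}

#' Named configuration presets
#'
#' Returns the structural variants analysed in the package:
#' \describe{
#'   \item{complete}{MtCK coupled to ANT, severe MOM restriction (0.007),
#'     MtCK fraction 31.25%.}
#'   \item{no_ck}{creatine kinase absent; unrestricted MOM so the system can
#'     run on ATP/ADP cycling alone.}
#'   \item{uncoupled_free}{CK present but uncoupled, no MOM restriction.}
#'   \item{coupled_no_restriction}{MtCK-ANT coupling on, no MOM restriction.}
#'   \item{system_A}{no coupling, MtCK fraction reduced to 8%, severe MOM
#'     restriction retained.}
#'   \item{no_coupling_weak_mom}{no coupling, MtCK 8%, weak restriction (0.1).}
#'   \item{reduced_pools}{as no_coupling_weak_mom plus 1.7-fold reduced
#'     adenine-nucleotide/creatine pools and 2.6-fold reduced Pi.}
#' }
#'
#' @param name preset name.
#' @return A [system_config()].
#' @examples
#' config_preset("complete")$mom_restriction_coeff # 0.007
#' @export
config_preset <- function(name = c("complete", "no_ck", "uncoupled_free",
                                   "coupled_no_restriction", "system_A",
                                   "no_coupling_weak_mom", "reduced_pools")) {
  name <- match.arg(name)
  switch(name,
    complete = system_config(),
    no_ck = system_config(ck_present = FALSE, coupling_enabled = FALSE,
                          mom_restriction_coeff = 1.0),
    uncoupled_free = system_config(coupling_enabled = FALSE,
                                   mom_restriction_coeff = 1.0),
    coupled_no_restriction = system_config(coupling_enabled = TRUE,
                                           mom_restriction_coeff = 1.0),
    system_A = system_config(coupling_enabled = FALSE,
                             mom_restriction_coeff = 0.007,
                             mtck_fraction = 0.08),
    no_coupling_weak_mom = system_config(coupling_enabled = FALSE,
                                         mom_restriction_coeff = 0.1,
                                         mtck_fraction = 0.08),
    reduced_pools = system_config(coupling_enabled = FALSE,
                                  mom_restriction_coeff = 0.1,
                                  mtck_fraction = 0.08,
                                  adn_cr_scale = 1.7, pi_scale = 2.6)
  )
}

#' @export
print.system_config <- function(x, ...) {
  cat("System configuration\n")
  cat(sprintf("  CK present:        %s\n", x$ck_present))
  cat(sprintf("  MtCK-ANT coupling: %s\n", x$coupling_enabled))
  cat(sprintf("  MOM restriction:   %g (PS base %g s^-1)\n",
              x$mom_restriction_coeff, x$mom_ps_base))
  cat(sprintf("  MtCK fraction:     %g\n", x$mtck_fraction))
  cat(sprintf("  pool scales:       ADN/Cr %g, Pi %g\n",
              x$adn_cr_scale, x$pi_scale))
  invisible(x)
}

#' Serialize a configuration to YAML or JSON
#'
#' @param config a [system_config()].
#' @param path output file; format chosen from the extension
#'   (`.yml`/`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "system_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config format: use .yaml or .json")
  }
  invisible(path)
}

#' Read a configuration from YAML or JSON
#'
#' @param path file written by [write_config()] (or hand-edited overrides of
#'   the same fields).
#' @return A [system_config()].
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: use .yaml or .json")
  }
  do.call(system_config, x)
}
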