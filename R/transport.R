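#' Transport parameters
#'
#' Diffusion coefficients per species and the grid spacing.  The
#' creatine/phosphocreatine pair and Pi move at free-solution-like rates;
#' adenine nucleotides are assigned a strongly reduced apparent diffusivity,
#' reflecting their binding to macromolecular complexes and the structural
#' crowding of the myofibrillar lattice.  This asymmetry is what makes the
#' creatine kinase shuttle the preferred spatial energy carrier.
#'
#' @param d_atp,d_adp,d_pcr,d_cr,d_pi diffusion coefficients, cm^2/s.
#' @param dx grid spacing, cm (1e-5 cm = 0.1 um).
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(d_atp = 8e-7, d_adp = 8e-7,
                             d_pcr = 2.3e-6, d_cr = 2.6e-6, d_pi = 3.0e-6,
                             dx = 1e-5) {
  d <- c(ATP = d_atp, ADP = d_adp, PCr = d_pcr, Cr = d_cr, Pi = d_pi)
  if (any(d <= 0) || dx <= 0) stop("diffusion coefficients and dx must be positive")
  structure(list(diffusion_coeff = d, dx = dx), class = "transport_params")
}

#' Check explicit-scheme stability
#'
#' The explicit central-difference scheme requires
#' `dt < dx^2 / (2 * max(D))`.  Called before integration starts; a violation
#' is a configuration error, not a runtime surprise.
#'
#' @param tparams a [transport_params()].
#' @param dt time step, ms.
#' @return `TRUE` invisibly, or an error.
#' @export
check_stability <- function(tparams, dt) {
  stopifnot(inherits(tparams, "transport_params"))
  dt_s <- dt / 1000
  dt_max <- tparams$dx^2 / (2 * max(tparams$diffusion_coeff))
  if (dt_s >= dt_max) {
    stop(sprintf(
      "explicit-scheme stability violated: dt = %g ms >= limit %g ms",
      dt, dt_max * 1000))
  }
  invisible(TRUE)
}

#' Concentration field of one metabolite
#'
#' @param species one of `"ATP"`, `"ADP"`, `"PCr"`, `"Cr"`, `"Pi"`.
#' @param grid_conc concentrations on the spatial grid, mM (one value per
#'   grid unit, the last being the intermembrane space).
#' @param matrix_conc matrix-pool concentration, mM (`NA` for Cr and PCr,
#'   which do not enter the matrix).
#' @return An object of class `metabolite_field`.
#' @export
metabolite_field <- function(species = c("ATP", "ADP", "PCr", "Cr", "Pi"),
                             grid_conc, matrix_conc = NA_real_) {
  species <- match.arg(species)
  if (any(!is.finite(grid_conc)) || any(grid_conc < 0)) {
    stop("grid concentrations must be finite and >= 0")
  }
  if (species %in% c("Cr", "PCr") && !is.na(matrix_conc)) {
    stop(species, " has no matrix pool")
  }
  if (!is.na(matrix_conc) && matrix_conc < 0) stop("matrix_conc must be >= 0")
  structure(list(species = species, grid_conc = as.numeric(grid_conc),
                 matrix_conc = matrix_conc), class = "metabolite_field")
}

#' One explicit diffusion step
#'
#' Advances a metabolite field by one explicit central-difference step along
#' the diffusive chain (myofibrillar + cytosolic units), with no-flux
#' boundaries at the myofibril core and at the IMS/matrix boundary, plus the
#' permeability-law exchange across the mitochondrial outer membrane into the
#' IMS unit.  Matrix pools are untouched (matrix exchange is via carriers
#' only).  Volume-weighted mass is conserved.
#'
#' @param field a [metabolite_field()].
#' @param tparams a [transport_params()].
#' @param dt time step, ms.
#' @param geom a [grid_geometry()].
#' @param config a [system_config()] (supplies the MOM permeability).
#' @return the updated [metabolite_field()].
#' @export
diffusion_step <- function(field, tparams, dt, geom = grid_geometry(),
                           config = system_config()) {
  stopifnot(inherits(field, "metabolite_field"),
            inherits(tparams, "transport_params"),
            inherits(geom, "grid_geometry"))
  check_stability(tparams, dt)
  c0 <- field$grid_conc
  n <- geom$n_units
  if (length(c0) != n) stop("field length does not match geometry")
  dt_s <- dt / 1000
  k <- tparams$diffusion_coeff[[field$species]] / tparams$dx^2
  nd <- n - 1L                       # diffusive chain excludes the IMS unit
  x <- c0[seq_len(nd)]
  lap <- c(x[2] - x[1],
           x[-c(1, nd)] * -2 + x[-c(nd - 1, nd)] + x[-c(1, 2)],
           x[nd - 1] - x[nd])
  x_new <- x + dt_s * k * lap
  # MOM exchange between last cytosolic unit and IMS
  j <- mom_flux(c0[n], x[nd], field$species, config, geom)   # mmol/s/kg, IMS -> cyt
  v <- geom$unit_volumes
  x_new[nd] <- x_new[nd] + dt_s * j / v[nd]
  ims_new <- c0[n] - dt_s * j / v[n]
  metabolite_field(field$species, c(x_new, ims_new), field$matrix_conc)
}

#' Net flux across the mitochondrial outer membrane
#'
#' Linear permeability law `flux = coeff * PS * V_ims * (c_ims - c_cyt)`,
#' where the restriction coefficient applies to ATP and ADP only: creatine,
#' phosphocreatine and Pi always cross with the unrestricted permeability.
#' Positive flux is directed out of the intermembrane space.
#'
#' @param conc_ims,conc_cyt concentrations on the two sides, mM.
#' @param species metabolite name.
#' @param config a [system_config()].
#' @param geom a [grid_geometry()].
#' @return flux in mmol s^-1 kg wm^-1.
#' @export
mom_flux <- function(conc_ims, conc_cyt,
                     species = c("ATP", "ADP", "PCr", "Cr", "Pi"),
                     config = system_config(), geom = grid_geometry()) {
  species <- match.arg(species)
  stopifnot(inherits(config, "system_config"), inherits(geom, "grid_geometry"))
  if (any(c(conc_ims, conc_cyt) < 0)) stop("concentrations must be >= 0")
  coeff <- if (species %in% c("ATP", "ADP")) config$mom_restriction_coeff else 1.0
  v_ims <- geom$unit_volumes[geom$ims_index]
  coeff * config$mom_ps_base * v_ims * (conc_ims - conc_cyt)
}
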