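#' Construct the initial model state
#'
#' Builds a spatially uniform state whose volume-weighted totals of creatine
#' (Cr + PCr), adenine nucleotides (ATP + ADP, grid + matrix) and total
#' phosphate groups (3 ATP + 2 ADP + PCr + Pi) reproduce the tissue
#' composition, after the configuration's pool scalings.  Grid ADP is set
#' from the CK mass-action ratio at the chosen resting PCr/Cr; the free-Pi
#' pool is whatever the phosphate total leaves after ATP and PCr.
#'
#' @param comp a [heart_composition()].
#' @param config a [system_config()].
#' @param resting_pcr_cr_ratio starting myoplasmic PCr/Cr (the diastolic
#'   low-workload anchor, ~2.6).
#' @param geom a [grid_geometry()].
#' @param matrix_adn_mM total matrix adenine-nucleotide concentration, mM.
#' @param matrix_adp_frac starting ADP fraction of matrix adenine nucleotides.
#' @return An object of class `model_state`: list of [metabolite_field()]s
#'   plus the geometry.
#' @export
initial_state <- function(comp = heart_composition(),
                          config = system_config(),
                          resting_pcr_cr_ratio = 2.6,
                          geom = grid_geometry(comp = comp),
                          matrix_adn_mM = 10,
                          matrix_adp_frac = 0.05) {
  stopifnot(inherits(comp, "heart_composition"),
            inherits(config, "system_config"),
            inherits(geom, "grid_geometry"))
  if (resting_pcr_cr_ratio <= 0) stop("resting_pcr_cr_ratio must be positive")
  v <- geom$unit_volumes
  v_grid <- sum(v)
  v_m <- geom$matrix_volume

  to_amount <- function(content) content * comp$dry_mass_fraction / 1000 # mmol/kg wm

  # unscaled baseline pools
  adn_amount0 <- to_amount(comp$total_adn)
  cr_amount0 <- to_amount(comp$total_creatine)
  p_amount0 <- to_amount(comp$total_phosphate)

  # scaled adenine-nucleotide and creatine pools
  adn_amount <- adn_amount0 / config$adn_cr_scale
  cr_amount <- cr_amount0 / config$adn_cr_scale

  m_adn_amount <- matrix_adn_mM * v_m / config$adn_cr_scale
  if (m_adn_amount >= adn_amount) {
    stop("infeasible totals: matrix pool exceeds total adenine nucleotides")
  }
  adn_grid_conc <- (adn_amount - m_adn_amount) / v_grid
  r <- resting_pcr_cr_ratio
  keq <- 166  # mass-action anchor for the ADP split; full kinetics take over at run time
  atp_grid <- adn_grid_conc / (1 + 1 / (keq * r))
  adp_grid <- adn_grid_conc - atp_grid

  cr_tot_conc <- cr_amount / v_grid
  pcr_grid <- cr_tot_conc * r / (1 + r)
  cr_grid <- cr_tot_conc - pcr_grid

  # baseline free Pi from the unscaled phosphate-group balance (3 per ATP,
  # 2 per ADP, 1 per PCr), then Pi scaling
  atp_amount0 <- atp_grid * v_grid * config$adn_cr_scale +
    matrix_adn_mM * v_m * (1 - matrix_adp_frac)
  adp_amount0 <- adp_grid * v_grid * config$adn_cr_scale +
    matrix_adn_mM * v_m * matrix_adp_frac
  pcr_amount0 <- pcr_grid * v_grid * config$adn_cr_scale
  pi_amount0 <- p_amount0 - 3 * atp_amount0 - 2 * adp_amount0 - pcr_amount0
  if (pi_amount0 <= 0) {
    stop("infeasible totals: phosphate bound in ATP, ADP and PCr exceeds total phosphate")
  }
  pi_amount <- pi_amount0 / config$pi_scale
  pi_conc <- pi_amount / (v_grid + v_m)

  n <- geom$n_units
  state <- structure(list(
    ATP = metabolite_field("ATP", rep(atp_grid, n),
                           matrix_adn_mM * (1 - matrix_adp_frac) / config$adn_cr_scale),
    ADP = metabolite_field("ADP", rep(adp_grid, n),
                           matrix_adn_mM * matrix_adp_frac / config$adn_cr_scale),
    PCr = metabolite_field("PCr", rep(pcr_grid, n)),
    Cr = metabolite_field("Cr", rep(cr_grid, n)),
    Pi = metabolite_field("Pi", rep(pi_conc, n), pi_conc),
    geometry = geom
  ), class = "model_state")
  state
}

#' Volume-weighted totals of the conserved pools
#'
#' Returns the whole-tissue amounts (mmol per kg wet mass) of the three
#' conserved quantities: total creatine (Cr + PCr), total adenine
#' nucleotides (ATP + ADP, grid + matrix) and total phosphate groups
#' (3 ATP + 2 ADP + PCr + Pi).
#'
#' @param state a [initial_state()] or the state of a finished run.
#' @return named numeric vector `c(creatine=, adn=, phosphate=)`.
#' @export
state_totals <- function(state) {
  stopifnot(inherits(state, "model_state"))
  g <- state$geometry
  v <- g$unit_volumes
  v_m <- g$matrix_volume
  amt <- function(f) {
    sum(f$grid_conc * v) + if (is.na(f$matrix_conc)) 0 else f$matrix_conc * v_m
  }
  c(creatine = amt(state$Cr) + amt(state$PCr),
    adn = amt(state$ATP) + amt(state$ADP),
    phosphate = 3 * amt(state$ATP) + 2 * amt(state$ADP) + amt(state$PCr) +
      amt(state$Pi))
}

#' @export
print.model_state <- function(x, ...) {
  g <- x$geometry
  tot <- state_totals(x)
  cat(sprintf("Model state on %d grid units + matrix pool\n", g$n_units))
  cat(sprintf("  totals (mmol/kg wm): Cr+PCr %.3f, ATP+ADP %.3f, ~P %.3f\n",
              tot["creatine"], tot["adn"], tot["phosphate"]))
  invisible(x)
}
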