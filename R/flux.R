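#' Cycle-averaged flux summary
#'
#' Computes the energy bookkeeping of one converged contraction cycle:
#' cycle-mean synthase, translocase, MtCK and MM-CK fluxes, the net export of
#' ATP and PCr through the mitochondrial outer membrane, the resulting
#' percentage partition of mitochondrial energy export between PCr and ATP,
#' the oxygen uptake implied by the synthase flux, the PCr/O2 ratio and the
#' end-diastolic myoplasmic PCr/Cr ratio.  Export fractions use the net
#' cycle effluxes only; matrix/IMS storage drift is excluded from the
#' denominator and reported separately.
#'
#' @param run a `ck_run` from [run_to_cyclic_steady_state()].
#' @param comp a [heart_composition()].
#' @param stoich a [stoichiometry()].
#' @return An object of class `cycle_flux_summary` (a one-row list).
#' @export
summarize_cycle <- function(run, comp = heart_composition(),
                            stoich = stoichiometry()) {
  stopifnot(inherits(run, "ck_run"))
  if (!isTRUE(run$converged)) {
    stop(sprintf("trace is not from a converged cycle (residual %.3g)",
                 run$residual))
  }
  last <- run$cycles[nrow(run$cycles), ]
  syn <- last$synthase_flux
  atp_exp <- last$mom_atp
  adp_ret <- -last$mom_adp            # ADP returning into the IMS
  pcr_exp <- last$mom_pcr
  total_exp <- atp_exp + pcr_exp
  pcr_fraction <- if (abs(total_exp) > 0) 100 * pcr_exp / total_exp else NA_real_
  vo2 <- atp_rate_to_vo2(max(syn, 0), stoich, comp)
  o2 <- syn / stoich$atp_per_o2
  structure(list(
    synthase_flux = syn,
    ant_flux = last$ant_flux,
    atpase_flux = last$atpase_flux,
    mtck_net_flux = last$mtck_net_flux,
    mmck_net_flux = -last$mmck_pcr_flux,  # ATP-regenerating direction
    atp_mom_export = atp_exp,
    adp_mom_return = adp_ret,
    pcr_mom_export = pcr_exp,
    pcr_fraction = pcr_fraction,
    atp_fraction = if (is.na(pcr_fraction)) NA_real_ else 100 - pcr_fraction,
    # synthase output either leaves as ATP or is transphosphorylated by MtCK;
    # the remainder is matrix/IMS storage drift (small at cyclic steady state)
    storage_drift = syn - (atp_exp + last$mtck_net_flux),
    vo2 = vo2,
    pcr_o2 = if (o2 > 0) pcr_exp / o2 else NA_real_,
    diastolic_pcr_cr = last$diastolic_pcr_cr
  ), class = "cycle_flux_summary")
}

#' @export
print.cycle_flux_summary <- function(x, ...) {
  cat(sprintf("  synthase %.3f | MtCK %.3f | MM-CK %.3f mmol/s/kg\n",
              x$synthase_flux, x$mtck_net_flux, x$mmck_net_flux))
  cat(sprintf("  MOM export: PCr %.3f (%.1f%%), ATP %.3f (%.1f%%)\n",
              x$pcr_mom_export, x$pcr_fraction,
              x$atp_mom_export, x$atp_fraction))
  cat(sprintf("  VO2 %.1f umol O2/min/g dwt | PCr/O2 %.2f | diastolic PCr/Cr %.2f\n",
              x$vo2, x$pcr_o2, x$diastolic_pcr_cr))
  invisible(x)
}

#' Fit the mitochondrial response time constant
#'
#' Least-squares mono-exponential fit
#' `VO2(t) = V_after - (V_after - V_before) * exp(-t / tau)` with both
#' asymptotes free.  For each candidate tau the asymptotes are solved by
#' linear least squares; tau is then found by one-dimensional minimisation of
#' the profiled residual sum of squares.
#'
#' @param vo2_series data frame with columns `time` (s, from the step
#'   instant) and `vo2`.
#' @return list with `t_mito` (s), `v_before`, `v_after`, `r_squared`.  A
#'   flat series is an error; a fit with R^2 < 0.95 attaches a warning.
#' @export
fit_tmito <- function(vo2_series) {
  stopifnot(is.data.frame(vo2_series),
            all(c("time", "vo2") %in% names(vo2_series)))
  t <- vo2_series$time
  y <- vo2_series$vo2
  if (length(t) < 4) stop("undefined t_mito: series too short")
  if (stats::sd(y) < 1e-9 * (abs(mean(y)) + 1e-12)) {
    stop("undefined t_mito: VO2 series is flat")
  }
  sse <- function(log_tau) {
    b <- exp(-t / exp(log_tau))
    fit <- stats::lm.fit(cbind(1, b), y)
    sum(fit$residuals^2)
  }
  span <- max(t) - min(t)
  opt <- stats::optimize(sse, interval = log(c(span * 1e-4, span * 10)))
  tau <- exp(opt$minimum)
  b <- exp(-t / tau)
  fit <- stats::lm.fit(cbind(1, b), y)
  v_after <- fit$coefficients[1]
  v_before <- v_after + fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  if (r2 < 0.95) {
    warning(sprintf("poor mono-exponential fit: R^2 = %.3f", r2))
  }
  list(t_mito = unname(tau), v_before = unname(v_before),
       v_after = unname(v_after), r_squared = r2)
}

#' Workload-sweep summary and CK-flux linearity
#'
#' Assembles the per-workload table of oxygen uptake, fluxes, export
#' fractions and PCr/Cr, and fits the linear relation between the MM-CK net
#' flux and the respiration rate across the sweep.
#'
#' @param summaries list of [summarize_cycle()] results over >= 3 workloads.
#' @return list with `table` (data frame), `slope`, `intercept`, `r_squared`
#'   of the MM-CK flux vs VO2 regression.
#' @export
sweep_summary <- function(summaries) {
  if (length(summaries) < 3) stop("sweep requires at least 3 workloads")
  tab <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(vo2 = s$vo2, synthase_flux = s$synthase_flux,
               mtck_net_flux = s$mtck_net_flux,
               mmck_net_flux = s$mmck_net_flux,
               atp_mom_export = s$atp_mom_export,
               pcr_mom_export = s$pcr_mom_export,
               pcr_fraction = s$pcr_fraction, atp_fraction = s$atp_fraction,
               diastolic_pcr_cr = s$diastolic_pcr_cr)
  }))
  if (stats::sd(tab$vo2) < 1e-9) {
    stop("degenerate sweep: workloads do not vary")
  }
  fit <- stats::lm(mmck_net_flux ~ vo2, data = tab)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((tab$mmck_net_flux - mean(tab$mmck_net_flux))^2)
  list(table = tab,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - sse / sst)
}

#' Printed coupled MtCK/ANT rate table
#'
#' The published probability-model rates of PCr production (MtCK) and ATP
#' export (ANT), percent of maximum, as a function of medium ATP, together
#' with the printed PCr/O2 column.  Used as input for
#' [table1_consistency()].
#'
#' @return data frame with columns `atp_mM`, `mtck_rate_rel`, `ant_rate_rel`,
#'   `pcr_o2_printed`.
#' @export
coupled_rate_table <- function() {
  data.frame(
    atp_mM = c(1, 2, 5, 10),
    mtck_rate_rel = c(62.61, 63.95, 64.83, 65.17),
    ant_rate_rel = c(53.55, 52.12, 46.19, 38.22),
    pcr_o2_printed = c(7.01, 7.36, 8.44, 10.2)
  )
}

#' Consistency of PCr/O2 with the coupled-rate columns
#'
#' Recomputes the PCr/O2 ratio of each row of a coupled MtCK/ANT rate table
#' from the two rate columns via [pcr_o2_from_rates()] and reports the
#' deviation from the printed column.
#'
#' @param rows data frame as returned by [coupled_rate_table()].
#' @param stoich a [stoichiometry()].
#' @return the input with columns `pcr_o2_computed` and `deviation` added.
#' @export
table1_consistency <- function(rows = coupled_rate_table(),
                               stoich = stoichiometry()) {
  stopifnot(all(c("mtck_rate_rel", "ant_rate_rel") %in% names(rows)))
  if (any(rows$ant_rate_rel <= 0)) stop("ANT rates must be positive")
  rows$pcr_o2_computed <- pcr_o2_from_rates(rows$mtck_rate_rel,
                                            rows$ant_rate_rel, stoich)
  if ("pcr_o2_printed" %in% names(rows)) {
    rows$deviation <- rows$pcr_o2_computed - rows$pcr_o2_printed
  }
  rows
}
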