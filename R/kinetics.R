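#' Pulsatile workload protocol
#'
#' ATP hydrolysis by the myofibrillar ATPase follows a triangular pulse within
#' each contraction-relaxation cycle: a linear rise to the peak at
#' `ramp_peak_time`, a linear fall to zero at `pulse_end_time`, then rest for
#' the remainder of the cycle.  The pulse is scaled so its cycle average
#' equals `mean_rate`.
#'
#' @param mean_rate cycle-mean ATP hydrolysis rate, mmol ATP s^-1 kg wm^-1.
#' @param cycle_duration cycle length, ms.
#' @param ramp_peak_time time of peak hydrolysis, ms.
#' @param pulse_end_time time at which hydrolysis returns to zero, ms.
#' @return An object of class `workload_protocol`.
#' @export
workload_protocol <- function(mean_rate, cycle_duration = 180,
                              ramp_peak_time = 30, pulse_end_time = 60) {
  if (!(ramp_peak_time > 0 && ramp_peak_time < pulse_end_time &&
        pulse_end_time < cycle_duration)) {
    stop("require 0 < ramp_peak_time < pulse_end_time < cycle_duration")
  }
  if (mean_rate < 0) stop("mean_rate must be >= 0")
  structure(list(
    mean_rate = mean_rate,
    cycle_duration = cycle_duration,
    ramp_peak_time = ramp_peak_time,
    pulse_end_time = pulse_end_time
  ), class = "workload_protocol")
}

#' Instantaneous ATPase rate within the contraction cycle
#'
#' @param t_in_cycle time, ms; values outside the cycle wrap modulo the cycle
#'   duration.
#' @param protocol a [workload_protocol()].
#' @return ATP hydrolysis rate in mmol s^-1 kg wm^-1.  The peak equals
#'   `mean_rate * 2 * cycle_duration / pulse_end_time` so the pulse integrates
#'   to `mean_rate * cycle_duration`.
#' @examples
#' p <- workload_protocol(1.5)
#' atpase_rate(30, p) # 9, the peak
#' @export
atpase_rate <- function(t_in_cycle, protocol) {
  stopifnot(inherits(protocol, "workload_protocol"))
  t <- t_in_cycle %% protocol$cycle_duration
  peak <- protocol$mean_rate * 2 * protocol$cycle_duration / protocol$pulse_end_time
  up <- t < protocol$ramp_peak_time
  down <- !up & t < protocol$pulse_end_time
  r <- numeric(length(t))
  r[up] <- peak * t[up] / protocol$ramp_peak_time
  r[down] <- peak * (protocol$pulse_end_time - t[down]) /
    (protocol$pulse_end_time - protocol$ramp_peak_time)
  r
}

#' Kinetic parameters of the reaction network
#'
#' Bundles the rate-law constants for all reactions.  Creatine kinase pools
#' follow a reversible random-order bi-bi law constrained by the Haldane
#' relation through `ck_keq`, defined as the equilibrium mass-action ratio
#' \[ATP\]\[Cr\]/(\[ADP\]\[PCr\]) (about 166 at physiological pH and Mg2+,
#' so net phosphocreatine synthesis requires an ATP/ADP ratio far above
#' equilibrium, as in the translocase microcompartment).  The ATP synthase is
#' a product of hyperbolic ADP and Pi saturation terms; the translocase (ANT)
#' is saturable in matrix ATP and intermembrane-space ADP; the Pi carrier is
#' saturable in IMS Pi.  Maximal rates of the mitochondrial carriers and the
#' microcompartment coupling gain are set by [calibrate()]; the defaults here
#' are the calibrated values for the complete configuration.
#'
#' @param ck_vmax_rev_total total cellular CK maximal rate in the reverse,
#'   ATP-producing direction, mmol s^-1 kg wm^-1.
#' @param ck_keq equilibrium \[ATP\]\[Cr\]/(\[ADP\]\[PCr\]) ratio.
#' @param mm_ka,mm_kb,mm_kic,mm_kd MM-CK constants: MgATP, Cr, MgADP, PCr (mM).
#' @param mt_kb,mt_kic,mt_kd MtCK constants: Cr, MgADP, PCr (mM) for the
#'   free (uncoupled) enzyme.
#' @param mt_kb_coupled,mt_kd_coupled Cr and PCr constants (mM) of the
#'   channeled, membrane-bound MtCK octamer: substrate affinity for creatine
#'   is higher and product binding of PCr weaker than for the free enzyme,
#'   reflecting vectorial substrate handling inside the Mitochondrial
#'   Interactosome.
#' @param mtck_ka_atp_invitro MtCK MgATP dissociation constant with direct
#'   access to translocase-supplied ATP (coupled/channeled state), mM.
#' @param mtck_ka_atp_invivo apparent MtCK MgATP dissociation constant for
#'   bulk cytosolic ATP reaching MtCK across the restricted outer membrane
#'   (uncoupled state in the intact cell), mM.
#' @param synthase_vmax,synthase_km_adp,synthase_km_pi ATP synthase maximal
#'   rate (mmol s^-1 kg wm^-1) and matrix-side Michaelis constants (mM).
#' @param ant_vmax,ant_km_adp,ant_km_atp translocase maximal rate and
#'   half-saturation constants for IMS ADP and matrix ATP (mM).
#' @param ant_hill Hill exponent of the ADP activation of the translocase
#'   (1 = hyperbolic).
#' @param ant_ratio_q back-pressure constant of the electrogenic exchange:
#'   translocase turnover is scaled by
#'   `adp / (adp + q * atp)` on the cytosolic side, i.e. inhibited by a high
#'   extramitochondrial ATP/ADP phosphorylation potential.  This reproduces
#'   the steep, declining-elasticity respiratory control by cytosolic ADP
#'   that thermodynamically explicit oxidative-phosphorylation models show:
#'   near the resting state respiration responds supra-linearly to ADP, and
#'   the sensitivity falls toward the maximal workload.
#' @param pic_vmax,pic_km Pi-carrier maximal rate and Michaelis constant.
#' @param coupling_gain local ATP amplification in the MtCK-ANT
#'   microcompartment, mM per (mmol s^-1 kg wm^-1) of translocase flux in
#'   the high-turnover limit.
#' @param coupling_jhalf translocase flux at which the microcompartment
#'   accumulation reaches half its high-turnover efficiency
#'   (mmol s^-1 kg wm^-1); the local ATP excess is
#'   `gain * J^2 / (J + jhalf)`, i.e. accumulation is quadratic at low
#'   turnover and linear at high turnover.
#' @param coupling_capture maximal fraction of the translocase ATP output
#'   that the coupled MtCK can intercept before it escapes the
#'   microcompartment (local mass balance of the channeled ATP).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(ck_vmax_rev_total = 64,
                           ck_keq = 166,
                           mm_ka = 0.9, mm_kb = 15.5, mm_kic = 0.2, mm_kd = 1.6,
                           mt_kb = 5.2, mt_kic = 0.204, mt_kd = 0.45,
                           mt_kb_coupled = 2.5, mt_kd_coupled = 15,
                           mtck_ka_atp_invitro = 0.016,
                           mtck_ka_atp_invivo = 2.04,
                           synthase_vmax = 14.08,
                           synthase_km_adp = 0.02,
                           synthase_km_pi = 1.0,
                           ant_vmax = 26.6,
                           ant_km_adp = 0.2,
                           ant_km_atp = 0.5,
                           ant_hill = 1,
                           ant_ratio_q = 0.008,
                           pic_vmax = 10.56,
                           pic_km = 1.0,
                           coupling_gain = 15,
                           coupling_jhalf = 15,
                           coupling_capture = 0.95) {
  p <- list(
    ck_vmax_rev_total = ck_vmax_rev_total, ck_keq = ck_keq,
    mm_ka = mm_ka, mm_kb = mm_kb, mm_kic = mm_kic, mm_kd = mm_kd,
    mt_kb = mt_kb, mt_kic = mt_kic, mt_kd = mt_kd,
    mt_kb_coupled = mt_kb_coupled, mt_kd_coupled = mt_kd_coupled,
    mtck_ka_atp_invitro = mtck_ka_atp_invitro,
    mtck_ka_atp_invivo = mtck_ka_atp_invivo,
    synthase_vmax = synthase_vmax,
    synthase_km_adp = synthase_km_adp, synthase_km_pi = synthase_km_pi,
    ant_vmax = ant_vmax, ant_km_adp = ant_km_adp, ant_km_atp = ant_km_atp,
    ant_hill = ant_hill, ant_ratio_q = ant_ratio_q,
    pic_vmax = pic_vmax, pic_km = pic_km,
    coupling_gain = coupling_gain,
    coupling_jhalf = coupling_jhalf,
    coupling_capture = coupling_capture
  )
  if (any(!is.finite(unlist(p))) || any(unlist(p) <= 0)) {
    stop("all kinetic parameters must be positive and finite")
  }
  if (coupling_capture <= 0 || coupling_capture > 1) {
    stop("coupling_capture must be in (0, 1]")
  }
  if (mtck_ka_atp_invivo <= mtck_ka_atp_invitro) {
    stop("mtck_ka_atp_invivo must exceed mtck_ka_atp_invitro")
  }
  structure(p, class = "kinetic_params")
}

#' Creatine kinase pool parameterization
#'
#' Builds the constants of one CK pool for [ck_rate()].  A pool is specified
#' by its maximal rate in either direction; the opposite-direction maximum is
#' implied by the Haldane relation
#' `Vmax_rev = Vmax_fwd * keq * kic * kd / (ka * kb)`.
#'
#' @param vmax maximal rate, mmol s^-1 kg wm^-1.
#' @param direction direction in which `vmax` is specified: `"forward"` is
#'   PCr-producing (ATP + Cr -> ADP + PCr), `"reverse"` is ATP-producing.
#' @param ka,kb,kic,kd MgATP, Cr, MgADP and PCr constants, mM.
#' @param keq equilibrium \[ATP\]\[Cr\]/(\[ADP\]\[PCr\]) ratio.
#' @return An object of class `ck_pool`.
#' @export
ck_pool <- function(vmax, direction = c("reverse", "forward"),
                    ka, kb, kic, kd, keq = 166) {
  direction <- match.arg(direction)
  stopifnot(vmax > 0, ka > 0, kb > 0, kic > 0, kd > 0, keq > 0)
  vmax_f <- if (direction == "forward") vmax else vmax * ka * kb / (keq * kic * kd)
  structure(list(vmax_f = vmax_f, ka = ka, kb = kb, kic = kic, kd = kd,
                 keq = keq), class = "ck_pool")
}

#' Net creatine kinase rate
#'
#' Reversible random-order bi-bi rate law.  Positive rates are PCr-producing
#' (ATP + Cr -> ADP + PCr); the expression vanishes exactly at the CK
#' equilibrium \[ATP\]\[Cr\] = keq \[ADP\]\[PCr\] and saturates at the
#' Haldane-consistent maximal rates in both directions.
#'
#' @param atp,adp,pcr,cr concentrations, mM (non-negative).
#' @param pool a [ck_pool()].
#' @return net rate in the units of the pool's vmax.
#' @export
ck_rate <- function(atp, adp, pcr, cr, pool) {
  stopifnot(inherits(pool, "ck_pool"))
  if (any(c(atp, adp, pcr, cr) < 0)) stop("concentrations must be >= 0")
  num <- atp * cr - pool$keq * adp * pcr
  den <- (1 + atp / pool$ka + adp / pool$kic) *
    (1 + cr / pool$kb + pcr / pool$kd)
  pool$vmax_f * num / (pool$ka * pool$kb * den)
}

#' Effective ATP concentration seen by mitochondrial creatine kinase
#'
#' With MtCK-ANT coupling enabled, translocase flux transiently raises the
#' ATP concentration in the 10-nm microcompartment between the two proteins
#' above the bulk intermembrane-space value; without coupling MtCK sees bulk
#' IMS ATP only.
#'
#' @param atp_ims bulk IMS ATP, mM.
#' @param ant_atp_flux translocase ATP export flux, mmol s^-1 kg wm^-1.
#' @param coupling_gain mM per (mmol s^-1 kg wm^-1) at high turnover.
#' @param coupling_enabled logical.
#' @param coupling_jhalf half-efficiency translocase flux, mmol s^-1 kg wm^-1.
#' @return effective ATP concentration, mM; strictly greater than `atp_ims`
#'   whenever coupling is on and the translocase flux is positive.
#' @export
mtck_effective_atp <- function(atp_ims, ant_atp_flux, coupling_gain,
                               coupling_enabled, coupling_jhalf = 2.0) {
  if (any(c(atp_ims, coupling_gain, coupling_jhalf) < 0)) {
    stop("inputs must be >= 0")
  }
  if (isTRUE(coupling_enabled)) {
    j <- pmax(ant_atp_flux, 0)
    atp_ims + coupling_gain * j^2 / (j + coupling_jhalf)
  } else {
    atp_ims
  }
}

#' ATP synthase rate
#'
#' @param adp_matrix,pi_matrix matrix concentrations, mM.
#' @param params a [kinetic_params()].
#' @return rate in mmol s^-1 kg wm^-1.
#' @export
synthase_rate <- function(adp_matrix, pi_matrix, params = kinetic_params()) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(c(adp_matrix, pi_matrix) < 0)) stop("concentrations must be >= 0")
  params$synthase_vmax *
    adp_matrix / (adp_matrix + params$synthase_km_adp) *
    pi_matrix / (pi_matrix + params$synthase_km_pi)
}

#' Adenine nucleotide translocase rate
#'
#' Exchange of matrix ATP for intermembrane-space ADP: saturable in both
#' substrates and opposed by the cytosolic-side phosphorylation potential
#' (see `ant_ratio_q` in [kinetic_params()]).  The rate is zero when either
#' substrate is absent.
#'
#' @param atp_matrix matrix ATP, mM.
#' @param adp_ims IMS ADP, mM.
#' @param params a [kinetic_params()].
#' @param atp_ims IMS ATP, mM (cytosolic-side back-pressure).
#' @return ATP export rate in mmol s^-1 kg wm^-1.
#' @export
ant_rate <- function(atp_matrix, adp_ims, params = kinetic_params(),
                     atp_ims = 0) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(c(atp_matrix, adp_ims, atp_ims) < 0)) stop("concentrations must be >= 0")
  if (all(adp_ims == 0)) return(adp_ims * 0)
  x <- (adp_ims / params$ant_km_adp)^params$ant_hill
  den <- adp_ims + params$ant_ratio_q * atp_ims
  back <- ifelse(den > 0, adp_ims / den, 0)
  params$ant_vmax *
    atp_matrix / (atp_matrix + params$ant_km_atp) *
    x / (1 + x) * back
}

#' Phosphate carrier rate
#'
#' Saturable, reversible Pi exchange between the intermembrane space and the
#' matrix; net uptake is positive when IMS Pi exceeds matrix Pi and vanishes
#' when the two sides are balanced, so the carrier cannot pump the cytosolic
#' Pi pool dry.
#'
#' @param pi_ims IMS Pi, mM.
#' @param params a [kinetic_params()].
#' @param pi_matrix matrix Pi, mM.
#' @return net uptake rate in mmol s^-1 kg wm^-1.
#' @export
pic_rate <- function(pi_ims, params = kinetic_params(), pi_matrix = 0) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(c(pi_ims, pi_matrix) < 0)) stop("concentrations must be >= 0")
  params$pic_vmax * (pi_ims - pi_matrix) /
    (params$pic_km + pi_ims + pi_matrix)
}

# CK pools implied by a configuration: the myofibrillar/cytosolic pool keeps
# the measured reverse-direction activity; the coupled MtCK is parameterised
# by its forward (PCr-producing) capacity, equal to its activity share, with
# the channeled (in-vitro) MgATP affinity; the uncoupled MtCK is the bulk
# enzyme with the in-vivo apparent MgATP affinity.
ck_pools_for <- function(config, params) {
  if (!config$ck_present) return(list(mm = NULL, mt = NULL))
  vr_mm <- (1 - config$mtck_fraction) * params$ck_vmax_rev_total
  mm <- ck_pool(vr_mm, "reverse", ka = params$mm_ka, kb = params$mm_kb,
                kic = params$mm_kic, kd = params$mm_kd, keq = params$ck_keq)
  v_mt <- config$mtck_fraction * params$ck_vmax_rev_total
  mt <- if (config$mtck_fraction <= 0) {
    NULL
  } else {
    # forward (PCr-producing) capacity equals the activity share in both
    # coupling states; only the apparent MgATP affinity switches
    ck_pool(v_mt, "forward",
            ka = if (config$coupling_enabled) params$mtck_ka_atp_invitro
                 else params$mtck_ka_atp_invivo,
            kb = if (config$coupling_enabled) params$mt_kb_coupled
                 else params$mt_kb,
            kic = params$mt_kic,
            kd = if (config$coupling_enabled) params$mt_kd_coupled
                 else params$mt_kd,
            keq = params$ck_keq)
  }
  list(mm = mm, mt = mt)
}
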