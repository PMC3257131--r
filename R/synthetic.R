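#' Specification for a synthetic working-heart data set
#'
#' Emulates a Frank-Starling working-heart experiment: oxygen uptake linear
#' in workload with multiplicative Gaussian noise, and a monotonically
#' decreasing PCr/Cr ratio.  The defaults span the physiological range of
#' the isolated working rat heart (VO2 from ~20 to ~174 umol O2/min/g dwt
#' over workloads 0.4-3.52 mmol ATP/s/kg wm).
#'
#' @param n_workloads number of workload levels.
#' @param workload_range range of mean ATPase rates, mmol/s/kg wm (within
#'   0-4).
#' @param vo2_slope umol O2/min/g dwt per unit workload; default is the
#'   stoichiometric conversion for the idealized heart at ATP/O2 = 6.
#' @param vo2_intercept umol O2/min/g dwt at zero workload.
#' @param noise_sd relative (multiplicative) noise standard deviation.
#' @param pcr_cr_max resting PCr/Cr ratio.
#' @param pcr_cr_halfload workload at which PCr/Cr has fallen to half its
#'   resting value, mmol/s/kg wm.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
working_heart_spec <- function(n_workloads = 12,
                               workload_range = c(0.4, 3.52),
                               vo2_slope = atp_rate_to_vo2(1),
                               vo2_intercept = 0,
                               noise_sd = 0.05,
                               pcr_cr_max = 2.8,
                               pcr_cr_halfload = 1.6,
                               seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(workload_range < 0) || any(workload_range > 4)) {
    stop("workload_range must lie within [0, 4]")
  }
  if (diff(workload_range) <= 0) stop("workload_range must be increasing")
  structure(list(n_workloads = as.integer(n_workloads),
                 workload_range = workload_range,
                 vo2_slope = vo2_slope, vo2_intercept = vo2_intercept,
                 noise_sd = noise_sd, pcr_cr_max = pcr_cr_max,
                 pcr_cr_halfload = pcr_cr_halfload,
                 seed = as.integer(seed)), class = "synthetic_spec")
}

#' Generate a synthetic working-heart data set
#'
#' Pure function of (spec, seed): the same spec always yields the same table.
#'
#' @param spec a [working_heart_spec()].
#' @return data frame with columns `workload`, `vo2`, `pcr_cr`.
#' @export
generate_working_heart_dataset <- function(spec = working_heart_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  w <- seq(spec$workload_range[1], spec$workload_range[2],
           length.out = spec$n_workloads)
  vo2_true <- spec$vo2_intercept + spec$vo2_slope * w
  pcr_cr_true <- spec$pcr_cr_max / (1 + w / spec$pcr_cr_halfload)
  vo2 <- vo2_true * (1 + stats::rnorm(length(w), 0, spec$noise_sd))
  pcr_cr <- pcr_cr_true * (1 + stats::rnorm(length(w), 0, spec$noise_sd))
  data.frame(workload = w, vo2 = vo2, pcr_cr = pmax(pcr_cr, 0))
}

#' Generate a synthetic oxygen-uptake step response
#'
#' Mono-exponential approach from `v_before` to `v_after` with time constant
#' `tau`, sampled at the contraction-cycle period, with optional relative
#' Gaussian noise.  Used as a known-truth input for [fit_tmito()].
#'
#' @param tau time constant, s (> 0).
#' @param v_before,v_after pre- and post-step VO2 levels.
#' @param noise_sd relative noise standard deviation.
#' @param seed integer seed.
#' @param t_max length of the series, s (default 6 tau).
#' @param dt_sample sampling interval, s (default one 180 ms cycle).
#' @return data frame with columns `time`, `vo2`.
#' @export
generate_step_response <- function(tau, v_before, v_after, noise_sd = 0,
                                   seed = 1L, t_max = 6 * tau,
                                   dt_sample = 0.18) {
  if (tau <= 0) stop("tau must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  t <- seq(dt_sample, t_max, by = dt_sample)
  vo2 <- v_after - (v_after - v_before) * exp(-t / tau)
  if (noise_sd > 0) {
    vo2 <- vo2 * (1 + stats::rnorm(length(t), 0, noise_sd))
  }
  data.frame(time = t, vo2 = vo2)
}
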