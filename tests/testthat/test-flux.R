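test_that("mono-exponential fitting recovers known time constants", {
  # noise-free recovery at the physiological and the slow regime
  for (tau in c(4, 15)) {
    s <- generate_step_response(tau, 20, 34, noise_sd = 0)
    fit <- fit_tmito(s)
    expect_equal(fit$t_mito, tau, tolerance = 0.01 / tau)
    expect_gt(fit$r_squared, 0.999)
  }
})

test_that("fitting tolerates measurement noise within Monte-Carlo bounds", {
  # bounds frozen from a 100-replicate Monte-Carlo run of this generator at
  # 2% relative noise: max |tau - 4| = 0.40, sd = 0.14
  taus <- vapply(1:20, function(seed) {
    fit_tmito(generate_step_response(4, 20, 34, noise_sd = 0.02,
                                     seed = seed))$t_mito
  }, numeric(1))
  expect_lt(max(abs(taus - 4)), 0.45)
  expect_lt(sd(taus), 0.17)
  expect_equal(mean(taus), 4, tolerance = 0.05)
})

test_that("degenerate response series are rejected", {
  flat <- data.frame(time = seq(0.18, 20, by = 0.18), vo2 = 25)
  expect_error(fit_tmito(flat), "flat")
  expect_error(fit_tmito(data.frame(time = 1:3, vo2 = c(1, 2, 3))), "short")
  noisy_flat <- generate_step_response(4, 25, 25.001, noise_sd = 0.05, seed = 2)
  expect_warning(fit_tmito(noisy_flat), "poor")
})

test_that("sweep summaries report the CK-flux/respiration regression", {
  mk_summary <- function(vo2, mmck) {
    structure(list(vo2 = vo2, synthase_flux = vo2 / 49.36,
                   mtck_net_flux = mmck, mmck_net_flux = mmck,
                   atp_mom_export = 0.1, pcr_mom_export = mmck,
                   pcr_fraction = 90, atp_fraction = 10,
                   diastolic_pcr_cr = 2), class = "cycle_flux_summary")
  }
  vo2 <- c(20, 60, 100, 140)
  exact <- lapply(seq_along(vo2), function(i) mk_summary(vo2[i], 0.018 * vo2[i]))
  sw <- sweep_summary(exact)
  expect_equal(sw$slope, 0.018, tolerance = 1e-12)
  expect_gt(sw$r_squared, 0.999999)
  expect_error(sweep_summary(exact[1:2]), "3")
  degenerate <- lapply(1:3, function(i) mk_summary(50, 1))
  expect_error(sweep_summary(degenerate), "degenerate")
})

test_that("cycle summaries refuse non-converged traces", {
  run <- steady_run("complete", 0.400)
  broken <- run
  broken$converged <- FALSE
  expect_error(summarize_cycle(broken), "not from a converged")
})

test_that("export fractions and energy bookkeeping close at steady state", {
  s <- steady_run("complete", 0.678)$summary
  expect_equal(s$pcr_fraction + s$atp_fraction, 100, tolerance = 0.1)
  # synthase output = direct ATP export + MtCK transphosphorylation + drift
  expect_lt(abs(s$storage_drift), 0.01 * s$synthase_flux)
  # adenine nucleotides cycle: ATP out is matched by ADP return
  expect_equal(s$adp_mom_return, s$atp_mom_export,
               tolerance = 0.02 * max(s$atp_mom_export, 1e-6))
})
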