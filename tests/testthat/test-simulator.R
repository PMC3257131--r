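test_that("identical inputs give bit-identical trajectories", {
  run_once <- function() {
    st <- initial_state()
    run_to_cyclic_steady_state(st, config_preset("complete"),
                               workload_protocol(0.678), fast_settings())
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$state, b$state)
  expect_identical(a$cycles, b$cycles)
  expect_identical(a$trace, b$trace)
})

test_that("conserved pools stay constant through a full simulation", {
  run <- steady_run("complete", 0.678)
  tot0 <- state_totals(initial_state(heart_composition(),
                                     config_preset("complete")))
  tot1 <- state_totals(run$state)
  expect_true(all(abs(tot1 / tot0 - 1) < 1e-9))
})

test_that("cycle-mean synthase flux balances the ATPase demand at steady state", {
  run <- steady_run("complete", 0.678)
  last <- run$cycles[nrow(run$cycles), ]
  expect_equal(last$synthase_flux, last$atpase_flux, tolerance = 0.01)
  # and the translocase carries the same cycle-mean flux
  expect_equal(last$ant_flux, last$synthase_flux, tolerance = 0.01)
})

test_that("a resting CK-free system relaxes to a flat trace", {
  st <- initial_state(heart_composition(), config_preset("no_ck"))
  # the final ADP decay is asymptotic, so a moderate tolerance suffices
  run <- run_to_cyclic_steady_state(st, config_preset("no_ck"),
                                    workload_protocol(0),
                                    sim_settings(steady_tol = 5e-4))
  last <- run$cycles[nrow(run$cycles), ]
  expect_lt(abs(last$synthase_flux), 5e-3)
  expect_lt(abs(last$mom_atp), 5e-3)
  expect_lt(diff(range(run$trace$ATP_u1)), 1e-4)
})

test_that("halving the time step leaves cycle-mean fluxes unchanged to 0.1%", {
  mk <- function(dt) {
    st <- initial_state()
    run_to_cyclic_steady_state(st, config_preset("complete"),
                               workload_protocol(0.678),
                               fast_settings(dt = dt))
  }
  a <- mk(0.01); b <- mk(0.005)
  la <- a$cycles[nrow(a$cycles), ]; lb <- b$cycles[nrow(b$cycles), ]
  for (col in c("synthase_flux", "mtck_net_flux", "mom_pcr")) {
    expect_equal(la[[col]], lb[[col]], tolerance = 1e-3)
  }
})

test_that("impossible demand is reported as a concentration failure", {
  st <- initial_state()
  expect_error(
    run_to_cyclic_steady_state(st, config_preset("complete"),
                               workload_protocol(80), fast_settings()),
    "negative concentration")
})

test_that("supply capacity is in excess: doubling synthase Vmax leaves VO2 unchanged", {
  p <- kinetic_params()
  p2 <- do.call(kinetic_params,
                modifyList(unclass(p), list(synthase_vmax = 2 * p$synthase_vmax)))
  mk <- function(par) {
    st <- initial_state()
    run_to_cyclic_steady_state(st, config_preset("complete"),
                               workload_protocol(3.52), fast_settings(), par)
  }
  expect_equal(mk(p2)$summary$vo2, mk(p)$summary$vo2, tolerance = 0.01)
})

test_that("an equal-load transition yields a flat series and undefined t_mito", {
  low <- steady_run("complete", 0.400)
  tr <- run_transition(low, 0.400)
  expect_true(is.na(tr$t_mito))
  expect_lt(diff(range(tr$vo2_series$vo2)), 0.05)
})

test_that("a workload step produces a rising oxygen-uptake response", {
  tr <- transition_run("complete")
  v <- tr$vo2_series$vo2
  expect_gt(tr$after$vo2, tr$before$vo2)
  # cycle-mean VO2 rises essentially monotonically toward the new state
  smoothed <- stats::filter(v, rep(1 / 5, 5), sides = 1)
  expect_true(all(diff(stats::na.omit(smoothed)) > -0.02))
})

test_that("calibration meets its anchors deterministically", {
  cal <- cached_run("calibration", function() calibrate(settings = std_settings()))
  ach <- attr(cal, "achieved")
  expect_equal(ach$vo2, 174, tolerance = 0.02)
  expect_equal(ach$pcr_cr, 2.64, tolerance = 0.10 * 2.64)
  cal2 <- calibrate(settings = std_settings(), verify = FALSE)
  expect_equal(cal$ant_vmax, cal2$ant_vmax)
})
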