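test_that("working-heart generator is a pure function of its spec", {
  spec <- working_heart_spec(seed = 7)
  expect_identical(generate_working_heart_dataset(spec),
                   generate_working_heart_dataset(spec))
  other <- generate_working_heart_dataset(working_heart_spec(seed = 8))
  expect_false(identical(generate_working_heart_dataset(spec), other))
})

test_that("noise-free synthetic data lie exactly on the stated relations", {
  spec <- working_heart_spec(noise_sd = 0)
  d <- generate_working_heart_dataset(spec)
  expect_equal(d$vo2, spec$vo2_intercept + spec$vo2_slope * d$workload)
  expect_true(all(diff(d$pcr_cr) < 0))
  # default span reaches the working-heart range
  expect_lt(min(d$vo2), 25)
  expect_gt(max(d$vo2), 170)
})

test_that("empirical noise level matches the specification", {
  spec <- working_heart_spec(n_workloads = 4000, noise_sd = 0.05, seed = 11)
  d <- generate_working_heart_dataset(spec)
  rel <- d$vo2 / (spec$vo2_intercept + spec$vo2_slope * d$workload) - 1
  expect_equal(sd(rel), 0.05, tolerance = 0.05 * 0.05 * 5)
})

test_that("step-response generator feeds the time-constant fit", {
  s <- generate_step_response(4, 19.7, 33.5, noise_sd = 0)
  expect_equal(fit_tmito(s)$t_mito, 4, tolerance = 1e-3)
  flat <- generate_step_response(4, 25, 25, noise_sd = 0)
  expect_true(all(flat$vo2 == 25))
  expect_error(generate_step_response(-1, 1, 2), "positive")
})

test_that("experiment manifests capture the run parameters", {
  m <- ckshuttle:::experiment_manifest("demo", config_preset("complete"),
                                       kinetic_params(), sim_settings(),
                                       list(workload = 1))
  expect_equal(m$experiment, "demo")
  expect_true(is.numeric(m$parameter_hash) && m$parameter_hash > 0)
  expect_equal(m$config$mom_restriction_coeff, 0.007)
})
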