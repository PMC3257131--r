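sealed_config <- function() system_config(mom_ps_base = 1e-9)

test_that("a uniform profile is a diffusion fixed point and mass is conserved", {
  geom <- grid_geometry()
  tp <- transport_params()
  f <- metabolite_field("Cr", rep(7.5, 13))
  f2 <- diffusion_step(f, tp, 0.01, geom, system_config())
  expect_equal(f2$grid_conc, rep(7.5, 13))

  set.seed(42)
  f <- metabolite_field("ATP", runif(13, 1, 10), 9)
  total0 <- sum(f$grid_conc * geom$unit_volumes)
  for (i in 1:200) f <- diffusion_step(f, tp, 0.01, geom, system_config())
  expect_equal(sum(f$grid_conc * geom$unit_volumes), total0,
               tolerance = 1e-12)
})

test_that("a single Fourier mode decays as exp(-D k^2 t)", {
  geom <- grid_geometry()
  tp <- transport_params()
  nd <- 12
  dx <- tp$dx
  k <- pi / (nd * dx)                      # slowest no-flux mode
  mode <- cos(k * ((seq_len(nd) - 0.5) * dx))
  base <- 10
  f <- metabolite_field("Cr", c(base + mode, base), NA_real_)
  dt <- 0.01
  n_steps <- 40                            # 0.4 ms
  cfg <- sealed_config()
  for (i in seq_len(n_steps)) f <- diffusion_step(f, tp, dt, geom, cfg)
  amp <- sum((f$grid_conc[1:nd] - base) * mode) / sum(mode^2)
  d <- tp$diffusion_coeff[["Cr"]]
  expected <- exp(-d * k^2 * n_steps * dt / 1000)
  expect_equal(amp, expected, tolerance = 5e-3)
})

test_that("outer-membrane flux is linear, selective and antisymmetric", {
  severe <- config_preset("complete")             # 0.007
  weak <- config_preset("no_coupling_weak_mom")   # 0.1
  none <- config_preset("uncoupled_free")         # 1.0
  expect_equal(mom_flux(5, 5, "ATP", severe), 0)
  # creatine and phosphocreatine are never restricted
  expect_equal(mom_flux(8, 3, "PCr", severe), mom_flux(8, 3, "PCr", none))
  expect_equal(mom_flux(8, 3, "Cr", severe), mom_flux(8, 3, "Cr", none))
  # ATP flux scales linearly with the restriction coefficient
  expect_equal(mom_flux(8, 3, "ATP", severe) / mom_flux(8, 3, "ATP", weak),
               0.07)
  expect_equal(mom_flux(3, 8, "ADP", weak), -mom_flux(8, 3, "ADP", weak))
})

test_that("explicit-scheme stability is checked before integration", {
  tp <- transport_params()
  expect_error(check_stability(tp, 0.05), "stability")
  expect_true(check_stability(tp, 0.01))
  expect_error(diffusion_step(metabolite_field("Pi", rep(1, 13), 1),
                              tp, 0.05), "stability")
})

test_that("metabolite fields validate their contents", {
  expect_error(metabolite_field("ATP", c(-1, rep(1, 12))), ">= 0")
  expect_error(metabolite_field("Cr", rep(1, 13), matrix_conc = 2),
               "matrix")
})
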