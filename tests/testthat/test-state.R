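test_that("constructed states reproduce the tissue composition exactly", {
  comp <- heart_composition()
  st <- initial_state(comp, config_preset("complete"))
  tot <- state_totals(st)
  to_amount <- function(x) x * comp$dry_mass_fraction / 1000
  expect_equal(unname(tot["creatine"]), to_amount(73))
  expect_equal(unname(tot["adn"]), to_amount(25))
  expect_equal(unname(tot["phosphate"]), to_amount(135))
  expect_true(all(vapply(c("ATP", "ADP", "PCr", "Cr", "Pi"),
                         function(s) all(st[[s]]$grid_conc >= 0), logical(1))))
})

test_that("pool scalings divide the creatine, nucleotide and Pi pools", {
  comp <- heart_composition()
  st <- initial_state(comp, config_preset("reduced_pools"))
  tot <- state_totals(st)
  to_amount <- function(x) x * comp$dry_mass_fraction / 1000
  expect_equal(unname(tot["creatine"]), to_amount(73) / 1.7)
  expect_equal(unname(tot["adn"]), to_amount(25) / 1.7)
  # free Pi is scaled 2.6-fold; bound phosphate scales with the ADN/Cr pools
  base <- initial_state(comp, config_preset("complete"))
  g <- st$geometry
  pi_amt <- function(s) sum(s$Pi$grid_conc * g$unit_volumes) +
    s$Pi$matrix_conc * g$matrix_volume
  expect_equal(pi_amt(st), pi_amt(base) / 2.6, tolerance = 1e-10)
})

test_that("grid ADP honours the creatine kinase mass-action anchor", {
  st <- initial_state(resting_pcr_cr_ratio = 2.2)
  ratio <- st$ATP$grid_conc[1] * st$Cr$grid_conc[1] /
    (st$ADP$grid_conc[1] * st$PCr$grid_conc[1])
  expect_equal(ratio, 166, tolerance = 1e-9)
  expect_equal(st$PCr$grid_conc[1] / st$Cr$grid_conc[1], 2.2)
})

test_that("infeasible compositions are rejected at construction", {
  lowp <- heart_composition(total_phosphate = 26)
  expect_error(initial_state(lowp), "phosphate")
  expect_error(initial_state(resting_pcr_cr_ratio = -1), "positive")
})
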