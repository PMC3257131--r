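test_that("tissue contents convert to molar concentrations", {
  comp <- heart_composition()
  # the canonical adenine-nucleotide conversion of the idealized heart
  expect_equal(content_to_molar(25, comp), 9.57, tolerance = 5e-4)
  expect_identical(content_to_molar(0, comp), 0)
  # forced arithmetic: 100 g dwt/kg in 1 L water/kg
  simple <- heart_composition(dry_mass_fraction = 100, matrix_water = 0.25,
                              extra_matrix_water = 0.75)
  expect_equal(content_to_molar(10, simple), 1.0)
  expect_error(content_to_molar(-1, comp), ">= 0")
})

test_that("content/molar conversions are mutually inverse", {
  comp <- heart_composition()
  for (x in c(0.1, 25, 73, 135)) {
    expect_equal(molar_to_content(content_to_molar(x, comp), comp), x)
  }
  alt <- heart_composition(dry_mass_fraction = 180, matrix_water = 0.12,
                           extra_matrix_water = 0.35)
  expect_equal(content_to_molar(molar_to_content(5.5, alt), alt), 5.5)
})

test_that("composition invariants are enforced", {
  expect_error(heart_composition(total_adn = 200), "total_adn")
  expect_error(heart_composition(matrix_water = 0.6, extra_matrix_water = 0.6),
               "water")
  expect_error(heart_composition(dry_mass_fraction = -1), "positive")
})

test_that("per-dry-mass recalculation coefficient reproduces cross-study conversion", {
  expect_equal(recalc_coefficient(435.2, 160, 155), 0.4216, tolerance = 1e-4)
  expect_equal(recalc_coefficient(1000, 123, 123), 1.0)
  expect_equal(recalc_coefficient(500, 100, 50), 0.25)
  expect_error(recalc_coefficient(435.2, 0, 155), "positive")
})

test_that("ATP turnover maps to working-heart oxygen uptake", {
  expect_equal(atp_rate_to_vo2(3.52), 174, tolerance = 2e-3)
  expect_identical(atp_rate_to_vo2(0), 0)
  # hand arithmetic: 0.4 * 1000 / 6 * 60 / 202.6
  expect_equal(atp_rate_to_vo2(0.4), 19.74, tolerance = 5e-4)
  # linearity and round trip
  expect_equal(atp_rate_to_vo2(2 * 1.3), 2 * atp_rate_to_vo2(1.3))
  expect_equal(vo2_to_atp_rate(atp_rate_to_vo2(2.2)), 2.2)
})

test_that("PCr/O2 follows from relative MtCK and translocase rates", {
  expect_equal(pcr_o2_from_rates(65.17, 38.22), 10.2, tolerance = 5e-3)
  expect_equal(pcr_o2_from_rates(62.61, 53.55), 7.01, tolerance = 1e-3)
  expect_equal(pcr_o2_from_rates(41.7, 41.7), 6.0)
  expect_error(pcr_o2_from_rates(50, 0), "undefined")
})

test_that("every printed coupled-rate row reproduces its PCr/O2 to 0.05", {
  tab <- table1_consistency(coupled_rate_table())
  expect_true(all(abs(tab$deviation) <= 0.05))
  fab <- data.frame(mtck_rate_rel = 30, ant_rate_rel = 30)
  expect_equal(table1_consistency(fab)$pcr_o2_computed, 6.0)
})
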