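test_that("pulsatile ATPase follows the triangular contraction profile", {
  p <- workload_protocol(1.5)
  expect_equal(atpase_rate(30, p), 9)      # peak = 6 x mean for 180/60 timing
  expect_equal(atpase_rate(15, p), 4.5)    # half-way up the ramp
  expect_equal(atpase_rate(90, p), 0)      # relaxed phase
  expect_equal(atpase_rate(90 + 180, p), 0)  # wraps modulo the cycle
  expect_equal(atpase_rate(210, p), atpase_rate(30, p))
  # the pulse integrates to mean_rate * cycle_duration (numeric oracle)
  tt <- seq(0, 180, by = 0.005); tt <- tt[-length(tt)]
  expect_equal(mean(atpase_rate(tt, p)), 1.5, tolerance = 1e-3)
  expect_error(workload_protocol(1, ramp_peak_time = 70), "ramp_peak_time")
  expect_error(workload_protocol(-1), ">= 0")
})

test_that("creatine kinase rate law obeys equilibrium, saturation and Haldane limits", {
  pool <- ck_pool(44, "reverse", ka = 0.9, kb = 15.5, kic = 0.2, kd = 1.6)
  # zero net rate at the mass-action equilibrium [ATP][Cr] = 166 [ADP][PCr]
  atp <- 8; cr <- 12; adp <- 0.05; pcr <- atp * cr / (166 * adp)
  expect_equal(ck_rate(atp, adp, pcr, cr, pool), 0, tolerance = 1e-12)
  # reverse saturation approaches -Vmax_rev (the Haldane-implied maximum)
  expect_equal(ck_rate(0, 1e6, 1e6, 0, pool), -44, tolerance = 1e-3)
  # forward saturation approaches the parameterised forward maximum
  fwd <- ck_pool(10, "forward", ka = 0.016, kb = 2.5, kic = 0.204, kd = 15)
  expect_equal(ck_rate(1e7, 0, 0, 1e7, fwd), 10, tolerance = 1e-3)
})

test_that("creatine kinase rate matches an independently coded expression", {
  # independent re-implementation of the random-order bi-bi law
  oracle <- function(atp, adp, pcr, cr, vf, ka, kb, kic, kd, keq) {
    e_num <- vf / (ka * kb)
    sat <- (1 + atp / ka + adp / kic) * (1 + cr / kb + pcr / kd)
    e_num * (atp * cr - keq * adp * pcr) / sat
  }
  pool <- ck_pool(20, "forward", ka = 0.9, kb = 5.2, kic = 0.204, kd = 0.45)
  cases <- expand.grid(atp = c(0.5, 9.4), adp = c(0.01, 0.4),
                       pcr = c(5, 27), cr = c(3, 30))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    expect_equal(ck_rate(cs$atp, cs$adp, cs$pcr, cs$cr, pool),
                 oracle(cs$atp, cs$adp, cs$pcr, cs$cr, pool$vmax_f, pool$ka,
                        pool$kb, pool$kic, pool$kd, pool$keq))
  }
})

test_that("microcompartment coupling raises the ATP seen by MtCK", {
  expect_equal(mtck_effective_atp(5, 3, 15, FALSE), 5)
  expect_equal(mtck_effective_atp(5, 0, 15, TRUE), 5)
  boosted <- mtck_effective_atp(5, 3, 15, TRUE)
  expect_gt(boosted, 5)
  # monotone in translocase flux
  expect_gt(mtck_effective_atp(5, 6, 15, TRUE), boosted)
})

test_that("coupled MtCK can make PCr from channeled ATP with no bulk IMS ATP", {
  params <- kinetic_params()
  atp_eff <- mtck_effective_atp(0, 5, params$coupling_gain, TRUE,
                                params$coupling_jhalf)
  pool <- ck_pool(20, "forward", ka = params$mtck_ka_atp_invitro,
                  kb = params$mt_kb_coupled, kic = params$mt_kic,
                  kd = params$mt_kd_coupled)
  expect_gt(ck_rate(atp_eff, 0.05, 10, 15, pool), 0)
  # without channeling the same bulk state cannot drive PCr synthesis
  expect_lt(ck_rate(0, 0.05, 10, 15, pool), 0)
})

test_that("mitochondrial carriers saturate and vanish without substrate", {
  p <- kinetic_params()
  expect_equal(synthase_rate(0, 5, p), 0)
  expect_equal(synthase_rate(5, 0, p), 0)
  expect_equal(synthase_rate(1e6, 1e6, p), p$synthase_vmax, tolerance = 1e-3)
  expect_equal(synthase_rate(p$synthase_km_adp, 1e7, p), p$synthase_vmax / 2,
               tolerance = 1e-3)
  expect_equal(ant_rate(5, 0, p), 0)
  expect_equal(ant_rate(0, 5, p), 0)
  expect_equal(pic_rate(0, p, 0), 0)
  expect_equal(pic_rate(1e7, p, 0), p$pic_vmax, tolerance = 1e-3)
})

test_that("translocase rate matches an independently coded expression", {
  p <- kinetic_params()
  oracle <- function(atp_m, adp, atp) {
    x <- adp / p$ant_km_adp
    p$ant_vmax * atp_m / (atp_m + p$ant_km_atp) * x / (1 + x) *
      adp / (adp + p$ant_ratio_q * atp)
  }
  for (cs in list(c(10, 0.02, 9.4), c(5, 0.3, 8), c(12, 0.05, 2))) {
    expect_equal(ant_rate(cs[1], cs[2], p, cs[3]), oracle(cs[1], cs[2], cs[3]))
  }
})

test_that("CK activity partitions between mitochondrial and myoplasmic pools", {
  params <- kinetic_params()
  pools <- ckshuttle:::ck_pools_for(config_preset("complete"), params)
  # the IMS pool carries the MtCK activity share in the PCr-producing direction
  expect_equal(pools$mt$vmax_f, 0.3125 * 64)
  # the myoplasmic pool keeps the remaining measured reverse activity
  vr_mm <- pools$mm$vmax_f * pools$mm$keq * pools$mm$kic * pools$mm$kd /
    (pools$mm$ka * pools$mm$kb)
  expect_equal(vr_mm, (1 - 0.3125) * 64)
  # no CK, no pools
  expect_null(ckshuttle:::ck_pools_for(config_preset("no_ck"), params)$mm)
})
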