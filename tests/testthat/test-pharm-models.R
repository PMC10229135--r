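test_that("saturation binding follows the one-site hyperbola", {
  bp <- binding_params(pKd_radioligand = 9, bmax = 1000)
  expect_equal(saturation_total_binding(1e-9, bp), 500)   # L = Kd
  expect_equal(saturation_total_binding(0, bp), 0)
  # hand arithmetic: Kd = 10^-9.76 = 1.738e-10, L = 1e-9
  bp2 <- binding_params(pKd_radioligand = 9.76, bmax = 1000)
  expect_equal(saturation_total_binding(1e-9, bp2),
               1000 / (1 + 10^-9.76 / 1e-9), tolerance = 1e-12)
  expect_lt(abs(saturation_total_binding(1e-9, bp2) - 851.9), 0.1)
  # nonspecific component is linear in L
  bp3 <- binding_params(pKd_radioligand = 9, bmax = 1000, ns_slope = 2)
  expect_equal(saturation_total_binding(1e-9, bp3), 500 + 2e-9)
  expect_error(saturation_total_binding(-1e-9, bp), ">= 0")
})

test_that("ternary complex occupancy reproduces the closed-form cases", {
  bp <- binding_params(pKd_radioligand = 6, pKi_agonist = 6,
                       pKb_modulator = 6, log_alpha = 0,
                       log_alpha_prime = 0)
  # simple competition at L* = Kd, no competitor: half occupancy
  expect_equal(atcm_fractional_occupancy(1e-6, 0, 0, bp), 0.5)
  # neutral modulator is invisible even at 10 x Kb
  expect_equal(atcm_fractional_occupancy(1e-6, 0, 10e-6, bp), 0.5)
  # L* = Kd, I = Ki: denominator doubles -> 1/3
  expect_equal(atcm_fractional_occupancy(1e-6, 1e-6, 0, bp), 1 / 3)
  expect_error(atcm_fractional_occupancy(-1e-6, 0, 0, bp), ">= 0")
  expect_error(atcm_fractional_occupancy(
    1e-6, 0, 0, binding_params(6, NA, 6)), "non-finite")
})

test_that("neutral-cooperativity occupancy equals Cheng-Prusoff competition", {
  bp <- binding_params(pKd_radioligand = 9.76, pKi_agonist = 4.5,
                       pKb_modulator = 5.65, log_alpha = 0,
                       log_alpha_prime = 0)
  Kast <- 10^-9.76; Ki <- 10^-4.5
  for (L in 10^seq(-11, -8, length.out = 10))
    for (I in c(0, 10^seq(-8, -3, length.out = 9)))
      for (B in c(0, 10^seq(-8, -4, length.out = 9))) {
        # with alpha = alpha' = 1 the modulator cancels exactly
        expect_equal(atcm_fractional_occupancy(L, I, B, bp),
                     L / (L + Kast * (1 + I / Ki)), tolerance = 1e-12)
      }
})

test_that("occupancy is monotone decreasing in the competitor", {
  tr <- human_wt_ly298_truth()
  bp <- binding_params(tr$pKd, tr$ACh$pKi, tr$pKb, tr$ACh$log_alpha)
  for (B in c(0, 1e-6, 1e-4)) {
    occ <- atcm_fractional_occupancy(10^-9.76,
                                     10^seq(-9, -1, 0.25), B, bp)
    expect_true(all(diff(occ) < 0))
    expect_true(all(occ >= 0 & occ <= 1))
  }
})

test_that("saturating modulator shifts agonist potency by the cooperativity factor", {
  tr <- human_wt_ly298_truth()
  for (ag in c("ACh", "Ipx")) {
    bp <- binding_params(tr$pKd, tr[[ag]]$pKi, tr$pKb,
                         tr[[ag]]$log_alpha, log_alpha_prime = 0)
    Kb <- 10^-tr$pKb
    shift <- atcm_ic50(bp, 0) / atcm_ic50(bp, 1e4 * Kb)
    expect_lt(abs(shift / 10^tr[[ag]]$log_alpha - 1), 0.05)
  }
})

test_that("operational agonism matches its closed-form cases", {
  fp <- functional_params(pKa_agonist = 6, log_tau_A = 1)
  # A = Ka, tau = 10: 100 * 10 / 12
  expect_equal(operational_agonism_response(1e-6, fp), 1000 / 12)
  expect_equal(operational_agonism_response(0, fp), 0)
  # ceiling em * tau / (1 + tau)
  expect_equal(operational_agonism_response(1, fp), 100 * 10 / 11,
               tolerance = 1e-4)
  fb <- functional_params(6, log_tau_A = 1, basal = 10)
  expect_equal(operational_agonism_response(0, fb), 10)
  expect_error(functional_params(6, n_slope = 0), "n_slope")
})

test_that("operational allosterism reduces correctly and matches hand arithmetic", {
  fp <- functional_params(pKa_agonist = 6, pKb_modulator = 6,
                          log_tau_A = 1, log_tau_B = 0,
                          log_alphabeta = 1, log_alpha = 1)
  A <- 10^seq(-10, -3, 0.5)
  expect_equal(operational_allosterism_response(A, 0, fp),
               operational_agonism_response(A, fp), tolerance = 1e-12)
  # hand oracle: N = 1.11e-10, D = 1.3e-11 -> 100 * N / (D + N)
  expect_equal(operational_allosterism_response(1e-6, 1e-6, fp),
               100 * 1.11e-10 / (1.3e-11 + 1.11e-10), tolerance = 1e-12)
  expect_equal(operational_allosterism_response(1e-6, 1e-6, fp),
               89.51613, tolerance = 1e-6)
  # silent modulator alone gives basal for all B
  fs <- functional_params(6, 6, log_tau_A = 1, log_tau_B = -Inf)
  expect_equal(operational_allosterism_response(0, 10^seq(-9, -3), fs),
               rep(0, 7))
})

test_that("operational allosterism is bounded and deterministic", {
  fp <- functional_params(5, 6, log_tau_A = 2, log_tau_B = 0.5,
                          log_alphabeta = 2, log_alpha = 1.5,
                          basal = 5)
  A <- rep(10^seq(-9, -2, 0.5), each = 8)
  B <- rep(c(0, 10^seq(-9, -4, length.out = 7)), 15)
  r1 <- operational_allosterism_response(A, B, fp)
  expect_true(all(r1 >= fp$basal - 1e-12 & r1 <= fp$em + 1e-12))
  expect_identical(r1, operational_allosterism_response(A, B, fp))
})

test_that("BRET ratio AUC integrates the baseline-corrected response", {
  times <- 0:40
  base_win <- c(0, 9)
  donor <- rep(1000, 41)
  veh_acc <- rep(1000, 41)
  # trace identical to vehicle -> 0
  r0 <- bret_ratio_auc(times, veh_acc, donor, veh_acc, donor, base_win)
  expect_equal(r0$auc, 0)
  # constant ratio step +0.2 after addition, 30 min window (t = 10..40)
  acc <- ifelse(times <= 9, 1000, 1200)
  r1 <- bret_ratio_auc(times, acc, donor, veh_acc, donor, base_win)
  expect_equal(r1$auc, 0.2 * 30)
  # negative-going response yields negative AUC
  accn <- ifelse(times <= 9, 1000, 800)
  expect_lt(bret_ratio_auc(times, accn, donor, veh_acc, donor,
                           base_win)$auc, 0)
  expect_error(bret_ratio_auc(times, acc[-1], donor[-1], veh_acc, donor,
                              base_win), "time grid")
  expect_error(bret_ratio_auc(times, acc, rep(0, 41), veh_acc, donor,
                              base_win), "donor")
})
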