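sat_design <- function() 10^seq(-11, -8, 0.25)

make_saturation_data <- function(bmax, pKd, replicate = 1L,
                                 noise_sd = 0, seed = NULL) {
  L <- sat_design()
  bp <- binding_params(pKd_radioligand = pKd, bmax = bmax)
  v <- saturation_total_binding(L, bp)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v * (1 + rnorm(length(v), 0, noise_sd))
  }
  assay_dataset(data.frame(radioligand_conc_M = L, value = v),
                "saturation", replicate = replicate)
}

test_that("saturation fit recovers noiseless truth to 4+ significant digits", {
  fit <- fit_saturation(make_saturation_data(598111, 9.76))
  expect_true(fit$converged)
  expect_equal(fit$estimates[["bmax"]], 598111, tolerance = 1e-5)
  expect_equal(fit$estimates[["pKd_radioligand"]], 9.76,
               tolerance = 1e-6)
})

test_that("all-zero saturation data is flagged degenerate", {
  ds <- assay_dataset(data.frame(radioligand_conc_M = sat_design(),
                                 value = 0), "saturation")
  fit <- fit_saturation(ds)
  expect_false(fit$converged)
  expect_true("degenerate" %in% fit$flags)
  expect_equal(fit$estimates[["bmax"]], 0)
})

test_that("noisy saturation replicates recover pKd within 0.1", {
  set.seed(11)
  ds <- lapply(1:3, function(r)
    make_saturation_data(598111, 9.76, replicate = r, noise_sd = 0.02))
  fit <- fit_saturation(ds)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["pKd_radioligand"]] - 9.76), 0.1)
  expect_equal(length(fit$per_replicate), 3)
  expect_true(is.finite(fit$sems[["pKd_radioligand"]]))
})

test_that("global ternary-complex fit recovers a neutral modulator", {
  truth <- binding_params(9.76, 5.0, 5.65, log_alpha = 0)
  ds <- simulate_interaction_binding(
    truth, make_interaction_design(truth), noise_model(sd = 0),
    n_experiments = 1, agonist = "ACh")
  fit <- fit_atcm_global(ds, pKd_radioligand = 9.76)
  expect_lt(abs(fit$estimates[["log_alpha.ACh"]]), 0.05)
  expect_lt(abs(fit$estimates[["pKi.ACh"]] - 5.0), 0.05)
})

test_that("global fit is reproducible from distinct random start sets", {
  ds <- simulate_binding_preset("human_wt_LY298", noise_model(sd = 0),
                                n_experiments = 1)
  ests <- sapply(c(1L, 2L, 3L), function(s)
    fit_atcm_global(ds, 9.76, seed = s, n_starts = 3)$estimates)
  expect_lt(max(abs(ests - ests[, 1])), 1e-4)
  truth <- c(pKi.ACh = 4.50, log_alpha.ACh = 2.59, pKi.Ipx = 8.30,
             log_alpha.Ipx = 1.86, pKb = 5.65)
  expect_lt(max(abs(ests[names(truth), 1] - truth)), 1e-4)
})

test_that("noisy ternary-complex recovery stays within 3 propagated SEMs", {
  ds <- simulate_binding_preset("human_wt_LY298",
                                noise_model(sd = 0.03),
                                n_experiments = 3, seed = 1)
  fit <- fit_atcm_global(ds, pKd_radioligand = 9.76)
  truth <- c(pKi.ACh = 4.50, log_alpha.ACh = 2.59, pKi.Ipx = 8.30,
             log_alpha.Ipx = 1.86, pKb = 5.65)
  for (nm in names(truth)) {
    expect_true(is.finite(fit$sems[[nm]]))
    expect_lt(abs(fit$estimates[[nm]] - truth[[nm]]),
              3 * fit$sems[[nm]] + 0.05)
  }
})

test_that("shared parameters are single estimates and fixing them costs ~nothing", {
  ds <- simulate_binding_preset("human_wt_LY298", noise_model(sd = 0),
                                n_experiments = 1)
  free_fit <- fit_atcm_global(ds, 9.76)
  # one shared pKb across both agonist datasets
  expect_equal(sum(names(free_fit$estimates) == "pKb"), 1)
  fixed_fit <- fit_atcm_global(
    ds, 9.76, spec = list(parameter_spec("pKb", 5.65, fixed = TRUE)))
  expect_lt(fixed_fit$residual_ss - free_fit$residual_ss, 1e-8)
})

test_that("few modulator levels triggers an identifiability warning", {
  truth <- binding_params(9.76, 5.0, 5.65, log_alpha = 1)
  g <- concentration_grid(10^seq(-8, -2, 0.5), c(0, 1e-6),
                          radioligand_conc = 10^-9.76)
  d <- g$grid
  d$value <- atcm_fractional_occupancy(d$radioligand_conc_M,
                                       d$agonist_conc_M,
                                       d$modulator_conc_M, truth)
  ds <- assay_dataset(d, "interaction_binding", agonist = "ACh")
  expect_warning(fit_atcm_global(list(ds), 9.76), "identifiabl")
})

test_that("operational fit recovers a silent modulator's functional cooperativity", {
  truth <- functional_params(pKa_agonist = 5, pKb_modulator = 5.5,
                             log_tau_A = 1.5, log_tau_B = -Inf,
                             log_alphabeta = 1.8, log_alpha = 1.5)
  ds <- simulate_functional_interaction(
    truth, make_interaction_design(truth), noise_model(sd = 0),
    n_experiments = 1, agonist = "ACh")
  fit <- fit_operational_allosterism_global(
    ds, c(pKa.ACh = 5, pKb = 5.5), log_alpha = 1.5)
  expect_lt(abs(fit$estimates[["log_alphabeta.ACh"]] - 1.8), 1e-3)
  # tau_B runs into its floor: modulator-alone curve is flat
  fitted_fp <- functional_params(5, 5.5, log_tau_A =
                                   fit$estimates[["log_tau_A.ACh"]],
                                 log_tau_B = fit$estimates[["log_tau_B"]],
                                 log_alphabeta =
                                   fit$estimates[["log_alphabeta.ACh"]],
                                 log_alpha = 1.5)
  alone <- operational_allosterism_response(0, 10^seq(-8, -4, 0.5),
                                            fitted_fp)
  expect_lt(max(alone) - min(alone), 0.5)
})

test_that("noisy functional recovery keeps log alphabeta within 0.2", {
  ds <- simulate_functional_preset("perk_wt_ACh_LY298",
                                   noise_model(sd = 3),
                                   n_experiments = 4, seed = 7)
  fit <- fit_operational_allosterism_global(
    ds, c(pKa.ACh = 4.51, pKb = 4.89),
    log_alpha = c(log_alpha.ACh = 1.97))
  expect_lt(abs(fit$estimates[["log_alphabeta.ACh"]] - 2.43), 0.2)
})

test_that("all-flat functional data is reported, not crashed on", {
  d <- data.frame(agonist_conc_M = 10^seq(-9, -4, 0.5),
                  modulator_conc_M = 0, value = 0)
  ds <- assay_dataset(d, "functional", agonist = "ACh")
  expect_warning(
    fit_operational_allosterism_global(list(ds),
                                       c(pKa.ACh = 5, pKb = 5.5)),
    "flat")
})

test_that("efficacy expression-correction follows log tau - log10(Bmax ratio)", {
  expect_equal(correct_efficacy_for_expression(1.0, 100, 100), 1.0)
  expect_equal(correct_efficacy_for_expression(1.0, 10, 100), 2.0)
  expect_equal(correct_efficacy_for_expression(1.0, 1000, 100), 0.0)
  expect_error(correct_efficacy_for_expression(1.0, 0, 100), "> 0")
})

test_that("SEM propagation is root-sum-square with its algebraic properties", {
  expect_equal(propagate_sem(c(0.3, 0)), 0.3)
  expect_equal(propagate_sem(c(0.07, 0.10)), 0.1221, tolerance = 1e-3)
  expect_equal(propagate_sem(c(0.1, 0.1, 0.1)), 0.1732, tolerance = 1e-3)
  expect_error(propagate_sem(c(0.1, -0.1)), ">= 0")
  set.seed(3)
  for (i in 1:20) {
    s <- runif(4)
    expect_equal(propagate_sem(s), propagate_sem(rev(s)))       # symmetric
    expect_equal(propagate_sem(2 * s), 2 * propagate_sem(s))    # degree 1
    expect_gte(propagate_sem(s), max(s))
  }
})

test_that("derived allosteric parameters match hand-computed oracles", {
  fit <- new_fit_result_for_test(
    estimates = c(pKb = 5.65, pKi.Ipx = 8.30, log_alpha.Ipx = 1.86,
                  log_alphabeta.Ipx = 2.01),
    sems = c(pKb = 0.07, pKi.Ipx = 0.06, log_alpha.Ipx = 0.10,
             log_alphabeta.Ipx = 0.14))
  out <- derived_parameters(fit)
  expect_equal(out$derived[["pKb_occupied.Ipx"]][1], 7.51)
  expect_equal(out$derived[["pKb_occupied.Ipx"]][2],
               sqrt(0.07^2 + 0.10^2))
  expect_equal(out$derived[["pKi_occupied.Ipx"]][1], 8.30 + 1.86)
  expect_equal(out$derived[["fold_alpha.Ipx"]][1], 10^1.86)
  expect_equal(out$derived[["log_beta.Ipx"]][1], 2.01 - 1.86)
  expect_equal(out$derived[["log_beta.Ipx"]][2],
               sqrt(0.14^2 + 0.10^2))
  # functional fit with binding cooperativity supplied externally
  ffit <- new_fit_result_for_test(
    estimates = c(log_alphabeta.ACh = 2.01),
    sems = c(log_alphabeta.ACh = 0.14))
  fout <- derived_parameters(ffit,
                             log_alpha = c(log_alpha.ACh = 2.59),
                             log_alpha_sem = c(log_alpha.ACh = 0.10))
  expect_equal(fout$derived[["log_beta.ACh"]][1], -0.58)
  expect_equal(fout$derived[["log_beta.ACh"]][2], 0.172,
               tolerance = 1e-3)
  # neutral cooperativity: fold 1, occupied = unoccupied affinity
  nfit <- new_fit_result_for_test(
    estimates = c(pKb = 5.65, log_alpha.ACh = 0),
    sems = c(pKb = 0.07, log_alpha.ACh = 0))
  nout <- derived_parameters(nfit)
  expect_equal(nout$derived[["fold_alpha.ACh"]][1], 1)
  expect_equal(nout$derived[["pKb_occupied.ACh"]][1], 5.65)
})

test_that("replicate summaries report mean, SEM and the table cell format", {
  mk <- function(v) new_fit_result_for_test(estimates = c(p = v),
                                            sems = c(p = NA))
  same <- summarize_replicates(list(mk(2), mk(2), mk(2)))
  expect_equal(same$sem, 0)
  s <- summarize_replicates(list(mk(1), mk(2), mk(3)))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$formatted, "2.00 ± 0.58 (3)")
  single <- summarize_replicates(list(mk(1.5)))
  expect_true(is.na(single$sem))
  expect_equal(format_pm(5.65, 0.07, 8), "5.65 ± 0.07 (8)")
  expect_equal(format_pm(NA, 0.1, 3), "N.D.")
})
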