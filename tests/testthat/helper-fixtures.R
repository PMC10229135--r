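# shared fixtures for the test suite

human_wt_ly298_truth <- function() {
  list(pKd = 9.76, pKb = 5.65,
       ACh = list(pKi = 4.50, log_alpha = 2.59),
       Ipx = list(pKi = 8.30, log_alpha = 1.86))
}

# numerically locate the agonist IC50 of the ATCM occupancy curve at a
# fixed modulator concentration (bisection on log10 I)
atcm_ic50 <- function(params, B, Lstar = 10^(-params$pKd_radioligand)) {
  top <- atcm_fractional_occupancy(Lstar, 0, B, params)
  f <- function(logI)
    atcm_fractional_occupancy(Lstar, 10^logI, B, params) - top / 2
  10^stats::uniroot(f, c(-16, 0), tol = 1e-12)$root
}

# quick GaMD settings for unit tests (production-scale runs live in the
# acceptance test)
quick_gamd_settings <- function(...) {
  gamd_settings(n_equil_cmd = 5000, n_equil_boost = 10000,
                n_prod = 50000, dt = 0.01, friction = 1,
                update_interval = 5000, ...)
}

count_well_crossings <- function(x, core = 0.5) {
  s <- sign(x[abs(x) > core])
  sum(diff(s) != 0)
}

# minimal fit_result construction for derived-parameter oracles
new_fit_result_for_test <- function(estimates, sems) {
  allomod:::new_fit_result(estimates, sems, 0, length(estimates), TRUE)
}
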