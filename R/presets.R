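#' Published pharmacological parameter sets used as generating truths
#'
#' Parameter sets for the M4 muscarinic receptor transcribed from
#' published radioligand-binding and functional interaction analyses of
#' the agonists acetylcholine (ACh) and iperoxo (Ipx) with the positive
#' allosteric modulators LY2033298 (LY298) and VU0467154 (VU154).
#' These are the truths the synthetic-data generators sample from and
#' the targets the parameter-recovery studies must reproduce.  Every
#' numeric field carries a provenance note naming its source row; the
#' same cells are checked in as
#' `system.file("extdata", "published_parameters.csv", package = "allomod")`
#' and a unit test cross-checks the two transcriptions.
#'
#' @return A named list of presets.  Binding presets hold
#'   `pKd_radioligand`, `pKb`, `log_alpha_prime` and a per-agonist list
#'   of `pKi` / `log_alpha`; functional presets hold per-agonist `pKa`,
#'   `log_tau_A`, `log_alphabeta`, `log_alpha` plus shared `pKb` and
#'   `log_tau_B`; saturation presets hold `bmax` and
#'   `pKd_radioligand`.
#' @export
truth_presets <- function() {
  list(
    human_wt_saturation = list(
      kind = "saturation", bmax = 598111, pKd_radioligand = 9.76,
      provenance = "saturation binding, human WT row"),
    mouse_wt_saturation = list(
      kind = "saturation", bmax = 21027, pKd_radioligand = 9.76,
      provenance = "saturation binding, mouse WT row"),

    human_wt_LY298 = list(
      kind = "binding", pKd_radioligand = 9.76, pKb = 5.65,
      log_alpha_prime = 0,
      agonists = list(
        ACh = list(pKi = 4.50, log_alpha = 2.59),
        Ipx = list(pKi = 8.30, log_alpha = 1.86)),
      provenance = "interaction binding, human WT x LY298 row"),
    human_wt_VU154 = list(
      kind = "binding", pKd_radioligand = 9.76, pKb = 5.83,
      log_alpha_prime = 0,
      agonists = list(
        ACh = list(pKi = 4.40, log_alpha = 1.61),
        Ipx = list(pKi = 8.19, log_alpha = 1.03)),
      provenance = "interaction binding, human WT x VU154 row"),
    mouse_wt_LY298 = list(
      kind = "binding", pKd_radioligand = 9.76, pKb = 5.74,
      log_alpha_prime = 0,
      agonists = list(
        ACh = list(pKi = 4.52, log_alpha = 1.78),
        Ipx = list(pKi = 8.55, log_alpha = 1.30)),
      provenance = "interaction binding, mouse WT x LY298 row"),
    mouse_wt_VU154 = list(
      kind = "binding", pKd_radioligand = 9.76, pKb = 6.07,
      log_alpha_prime = 0,
      agonists = list(
        ACh = list(pKi = 4.59, log_alpha = 2.43),
        Ipx = list(pKi = 8.57, log_alpha = 1.75)),
      provenance = "interaction binding, mouse WT x VU154 row"),
    q184a_LY298 = list(
      kind = "binding", pKd_radioligand = 9.99, pKb = 6.23,
      log_alpha_prime = -1.10,
      agonists = list(
        ACh = list(pKi = 5.24, log_alpha = 1.28),
        Ipx = list(pKi = 8.74, log_alpha = 1.27)),
      provenance = "mutant interaction binding, Q184A x LY298 row (radioligand cooperativity freed)"),

    perk_wt_ACh_LY298 = list(
      kind = "functional", pKb = 4.89, log_tau_B = 1.10,
      agonists = list(
        ACh = list(pKa = 4.51, log_tau_A = 2.96, log_alphabeta = 2.43,
                   log_alpha = 1.97)),
      provenance = "mutant-panel functional analysis, WT row (pERK1/2, ACh x LY298)"),
    trupath_wt_LY298 = list(
      kind = "functional", pKb = 5.65, log_tau_B = 1.02,
      agonists = list(
        ACh = list(pKa = 4.50, log_tau_A = 2.71, log_alphabeta = 2.01,
                   log_alpha = 2.59),
        Ipx = list(pKa = 8.30, log_tau_A = 1.49, log_alphabeta = 1.96,
                   log_alpha = 1.86)),
      provenance = "G-protein activation interaction assay, human WT x LY298 row; affinities fixed from binding"),
    trupath_wt_VU154 = list(
      kind = "functional", pKb = 5.83, log_tau_B = -0.55,
      agonists = list(
        ACh = list(pKa = 4.40, log_tau_A = 2.71, log_alphabeta = 1.22,
                   log_alpha = 1.61),
        Ipx = list(pKa = 8.19, log_tau_A = 1.49, log_alphabeta = 0.20,
                   log_alpha = 1.03)),
      provenance = "G-protein activation interaction assay, human WT x VU154 row; agonist efficacies shared with the LY298 row of the same assay"),
    perk_wt_LY298 = list(
      kind = "functional", pKb = 5.65, log_tau_B = 1.19,
      agonists = list(
        ACh = list(pKa = 4.50, log_tau_A = 3.27, log_alphabeta = 2.29,
                   log_alpha = 2.59),
        Ipx = list(pKa = 8.30, log_tau_A = 1.74, log_alphabeta = 1.08,
                   log_alpha = 1.86)),
      provenance = "pERK1/2 interaction assay, human WT x LY298 row"),
    perk_wt_VU154 = list(
      kind = "functional", pKb = 5.83, log_tau_B = 0.11,
      agonists = list(
        ACh = list(pKa = 4.40, log_tau_A = 3.27, log_alphabeta = 0.88,
                   log_alpha = 1.61),
        Ipx = list(pKa = 8.19, log_tau_A = 1.74, log_alphabeta = 0.66,
                   log_alpha = 1.03)),
      provenance = "pERK1/2 interaction assay, human WT x VU154 row; agonist efficacies shared with the LY298 row of the same assay")
  )
}
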