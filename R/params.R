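#' Pharmacological parameter sets for binding models
#'
#' Construct a validated parameter set for radioligand saturation and
#' allosteric ternary complex (ATCM) binding models.  All affinities and
#' cooperativities are handled in log10 space, matching the pK / log-alpha
#' conventions of the pharmacology literature.
#'
#' @param pKd_radioligand Negative log10 molar equilibrium dissociation
#'   constant of the radioligand (the orthosteric probe, e.g. an NMS-like
#'   antagonist).
#' @param pKi_agonist Negative log10 molar affinity of the orthosteric
#'   agonist for the unoccupied receptor.
#' @param pKb_modulator Negative log10 molar affinity of the allosteric
#'   modulator for the unoccupied receptor.
#' @param log_alpha log10 binding cooperativity between agonist and
#'   modulator (alpha > 1 means the modulator enhances agonist affinity).
#' @param log_alpha_prime log10 cooperativity between the radioligand and
#'   the modulator (0 = the modulator is neutral toward the probe).
#' @param bmax Maximal specific binding, in whatever units the assay is
#'   counted (sites/cell, dpm, or 1 for fractional binding). Must be > 0.
#' @param ns_slope Nonspecific binding per unit radioligand concentration
#'   (dimensionless, >= 0).
#' @return An object of class `binding_params` (a named list).
#' @examples
#' bp <- binding_params(pKd_radioligand = 9.76, pKi_agonist = 4.50,
#'                      pKb_modulator = 5.65, log_alpha = 2.59)
#' @export
binding_params <- function(pKd_radioligand,
                           pKi_agonist = NA_real_,
                           pKb_modulator = NA_real_,
                           log_alpha = 0,
                           log_alpha_prime = 0,
                           bmax = 1,
                           ns_slope = 0) {
  p <- list(pKd_radioligand = as.numeric(pKd_radioligand),
            pKi_agonist = as.numeric(pKi_agonist),
            pKb_modulator = as.numeric(pKb_modulator),
            log_alpha = as.numeric(log_alpha),
            log_alpha_prime = as.numeric(log_alpha_prime),
            bmax = as.numeric(bmax),
            ns_slope = as.numeric(ns_slope))
  if (!is.finite(p$pKd_radioligand))
    stop("pKd_radioligand must be finite")
  for (nm in c("log_alpha", "log_alpha_prime"))
    if (!is.finite(p[[nm]])) stop(nm, " must be finite")
  if (!is.finite(p$bmax) || p$bmax <= 0) stop("bmax must be > 0")
  if (!is.finite(p$ns_slope) || p$ns_slope < 0) stop("ns_slope must be >= 0")
  structure(p, class = "binding_params")
}

#' Pharmacological parameter sets for operational (functional) models
#'
#' Parameters of the Black-Leff operational model of agonism and its
#' extension to allosteric interactions.  Efficacies (tau) and
#' cooperativities are carried as log10 values.
#'
#' @param pKa_agonist Negative log10 molar functional affinity of the
#'   agonist (conventionally fixed from equilibrium binding).
#' @param pKb_modulator Negative log10 molar affinity of the modulator.
#' @param log_tau_A log10 operational efficacy of the orthosteric agonist.
#' @param log_tau_B log10 operational efficacy of the allosteric
#'   modulator (`-Inf` for a silent modulator).
#' @param log_alphabeta log10 functional cooperativity (alpha*beta).
#' @param log_alpha log10 binding cooperativity, used when separating the
#'   efficacy-modulation component beta.
#' @param em System maximal response; defaults to 100 (data normalized to
#'   the maximal agonist response).
#' @param n_slope Transducer slope factor, > 0; defaults to 1.
#' @param basal Response at zero ligand, in `[0, em)`.
#' @return An object of class `functional_params`.
#' @examples
#' fp <- functional_params(pKa_agonist = 4.51, pKb_modulator = 4.89,
#'                         log_tau_A = 2.96, log_tau_B = 1.10,
#'                         log_alphabeta = 2.43, log_alpha = 1.97)
#' @export
functional_params <- function(pKa_agonist,
                              pKb_modulator = NA_real_,
                              log_tau_A = 0,
                              log_tau_B = -Inf,
                              log_alphabeta = 0,
                              log_alpha = 0,
                              em = 100,
                              n_slope = 1,
                              basal = 0) {
  p <- list(pKa_agonist = as.numeric(pKa_agonist),
            pKb_modulator = as.numeric(pKb_modulator),
            log_tau_A = as.numeric(log_tau_A),
            log_tau_B = as.numeric(log_tau_B),
            log_alphabeta = as.numeric(log_alphabeta),
            log_alpha = as.numeric(log_alpha),
            em = as.numeric(em),
            n_slope = as.numeric(n_slope),
            basal = as.numeric(basal))
  if (!is.finite(p$pKa_agonist)) stop("pKa_agonist must be finite")
  if (!is.finite(p$em) || p$em <= 0) stop("em must be > 0")
  if (!is.finite(p$n_slope) || p$n_slope <= 0) stop("n_slope must be > 0")
  if (!is.finite(p$basal) || p$basal < 0 || p$basal >= p$em)
    stop("basal must satisfy 0 <= basal < em")
  # log_tau_B = -Inf encodes tau_B = 0 (no direct allosteric agonism)
  if (is.na(p$log_tau_B)) stop("log_tau_B must not be NA")
  structure(p, class = "functional_params")
}

#' Concentration grid for an assay design
#'
#' @param agonist_concs Molar agonist concentrations (0 allowed for
#'   vehicle).
#' @param modulator_concs Molar modulator concentrations (0 allowed).
#' @param radioligand_conc Molar radioligand concentration (binding
#'   assays); `NA` for functional assays.
#' @return Object of class `concentration_grid` whose `$grid` element is
#'   the fully crossed data frame of concentrations.
#' @export
concentration_grid <- function(agonist_concs, modulator_concs = 0,
                               radioligand_conc = NA_real_) {
  agonist_concs <- as.numeric(agonist_concs)
  modulator_concs <- as.numeric(modulator_concs)
  if (any(agonist_concs < 0) || any(modulator_concs < 0))
    stop("concentrations must be >= 0")
  if (!is.na(radioligand_conc) && radioligand_conc < 0)
    stop("radioligand_conc must be >= 0")
  if (!any(agonist_concs > 0))
    stop("at least one nonzero agonist concentration is required")
  g <- expand.grid(agonist_conc_M = agonist_concs,
                   modulator_conc_M = modulator_concs,
                   KEEP.OUT.ATTRS = FALSE)
  g$radioligand_conc_M <- radioligand_conc
  structure(list(agonist_concs = agonist_concs,
                 modulator_concs = modulator_concs,
                 radioligand_conc = radioligand_conc,
                 grid = g),
            class = "concentration_grid")
}
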