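#' Global fit of the operational model of allosterism and agonism
#'
#' Estimates operational efficacies (log tau_A per agonist, log tau_B
#' for the modulator, shared across agonist datasets by default) and the
#' functional cooperativity (log alphabeta per agonist) from functional
#' concentration-response interaction datasets.  Ligand binding
#' affinities (pKa per agonist, pKb for the modulator) and the binding
#' cooperativity (log alpha) are fixed from equilibrium binding assays,
#' as is conventional for this analysis.
#'
#' @param datasets List of [assay_dataset()] objects
#'   (`assay_kind = "functional"`), labelled with agonist and replicate.
#' @param fixed_affinities Named list/vector with elements
#'   `pKa.<agonist>` for every agonist present and `pKb` for the
#'   modulator.
#' @param log_alpha Binding cooperativity fixed from binding, either a
#'   scalar or a named vector `log_alpha.<agonist>`.
#' @param spec Optional list of [parameter_spec()] overrides
#'   (`log_tau_A.<agonist>`, `log_tau_B`, `log_alphabeta.<agonist>`,
#'   `em`, `basal`, `n_slope`).
#' @param share_tau_B If `TRUE` (default) one log tau_B is estimated
#'   across all agonist datasets.
#' @param fit_em If `TRUE`, the system maximum Em is estimated (one
#'   value shared across the datasets); default fixes Em at `em`.
#' @param em,basal,n_slope Fixed system parameters (response units /
#'   slope); defaults 100, 0 and 1 for data normalized to the maximal
#'   agonist response.
#' @param method,n_starts,seed As in [fit_atcm_global()].
#' @return A [`fit_result`][parameter_spec].
#' @export
fit_operational_allosterism_global <- function(datasets, fixed_affinities,
                                               log_alpha = 0,
                                               spec = NULL,
                                               share_tau_B = TRUE,
                                               fit_em = FALSE, em = 100,
                                               basal = 0, n_slope = 1,
                                               method = c("replicates",
                                                          "pooled"),
                                               n_starts = 5, seed = 0L) {
  method <- match.arg(method)
  stopifnot(all(vapply(datasets, function(d)
    d$assay_kind == "functional", TRUE)))
  fixed_affinities <- as.list(fixed_affinities)
  agonists <- unique(vapply(datasets, `[[`, "", "agonist"))
  for (ag in agonists)
    if (is.null(fixed_affinities[[paste0("pKa.", ag)]]))
      stop("fixed_affinities must supply pKa.", ag)
  if (is.null(fixed_affinities$pKb))
    stop("fixed_affinities must supply pKb")
  la <- function(ag) {
    if (length(log_alpha) == 1 && is.null(names(log_alpha)))
      return(as.numeric(log_alpha))
    v <- log_alpha[[paste0("log_alpha.", ag)]]
    if (is.null(v)) stop("log_alpha missing for agonist ", ag)
    as.numeric(v)
  }

  if (any(vapply(datasets, function(d)
    all(abs(d$data$value - d$data$value[1]) < 1e-12), TRUE)))
    warning("an all-flat response dataset was supplied")

  build_specs <- function(dsets) {
    specs <- list()
    for (ag in agonists) {
      d1 <- dsets[[which(vapply(dsets, `[[`, "", "agonist") == ag)[1]]]
      ctl <- d1$data[d1$data$modulator_conc_M == 0 &
                       d1$data$agonist_conc_M > 0, ]
      Ka <- 10^(-fixed_affinities[[paste0("pKa.", ag)]])
      # EC50 ~ Ka/(1+tau) for n = 1 gives a tau starting guess
      ec50 <- ctl$agonist_conc_M[which.min(abs(ctl$value -
                                                 max(ctl$value) / 2))]
      tau0 <- max(Ka / ec50 - 1, 0.1)
      specs <- c(specs, list(
        parameter_spec(paste0("log_tau_A.", ag), log10(tau0),
                       lower = -5, upper = 6),
        parameter_spec(paste0("log_alphabeta.", ag), 1,
                       lower = -5, upper = 5)))
    }
    specs <- c(specs, list(
      parameter_spec("log_tau_B", 0, lower = -5, upper = 6),
      parameter_spec("em", em, lower = 1e-6, upper = 10 * em,
                     fixed = !fit_em),
      parameter_spec("basal", basal, lower = 0, upper = em,
                     fixed = TRUE),
      parameter_spec("n_slope", n_slope, lower = 0.1, upper = 5,
                     fixed = TRUE)))
    merge_specs(specs, spec)
  }

  fit_group <- function(dsets) {
    specs <- build_specs(dsets)
    resid <- function(par) {
      p <- full_par(par, specs)
      unlist(lapply(dsets, function(d) {
        ltb <- if (share_tau_B) p$log_tau_B else
          p[[paste0("log_tau_B.", d$agonist)]]
        fp <- functional_params(
          pKa_agonist = fixed_affinities[[paste0("pKa.", d$agonist)]],
          pKb_modulator = fixed_affinities$pKb,
          log_tau_A = p[[paste0("log_tau_A.", d$agonist)]],
          log_tau_B = ltb,
          log_alphabeta = p[[paste0("log_alphabeta.", d$agonist)]],
          log_alpha = la(d$agonist),
          em = p$em, n_slope = p$n_slope, basal = p$basal)
        d$data$value - operational_allosterism_response(
          d$data$agonist_conc_M, d$data$modulator_conc_M, fp)
      }))
    }
    r <- fit_global_ls(resid, specs, n_starts = n_starts, seed = seed)
    n_pts <- sum(vapply(dsets, function(d) nrow(d$data), 0L))
    new_fit_result(r$par, r$sems, r$ss, n_pts, r$converged,
                   flags = if (!r$converged) "non-convergence" else
                     character())
  }

  if (method == "pooled") return(fit_group(datasets))
  reps <- vapply(datasets, `[[`, 0L, "replicate")
  fits <- lapply(sort(unique(reps)), function(rr)
    fit_group(datasets[reps == rr]))
  pool_replicates(fits)
}
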