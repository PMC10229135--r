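#' Fit saturation binding experiments
#'
#' Estimates `bmax`, `pKd_radioligand` and `ns_slope` from one or more
#' saturation binding experiments by bounded least squares.  Each
#' replicate experiment is fit separately and the replicate estimates
#' are summarized as mean +/- SEM, following the convention of
#' reporting independent experiments.
#'
#' @param datasets A list of [assay_dataset()] objects with
#'   `assay_kind = "saturation"` (or a single such object).
#' @param fit_ns If `TRUE` (default) the nonspecific slope is estimated;
#'   otherwise fixed at 0.
#' @param n_starts Number of multi-start Levenberg-Marquardt launches.
#' @param seed Seed for start jitter.
#' @return A [`fit_result`][parameter_spec] with pooled estimates
#'   (mean over replicates), SEMs, and per-replicate fits.
#' @export
fit_saturation <- function(datasets, fit_ns = TRUE, n_starts = 5,
                           seed = 0L) {
  if (inherits(datasets, "assay_dataset")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, function(d)
    d$assay_kind == "saturation", TRUE)))

  fit_one <- function(ds) {
    L <- ds$data$radioligand_conc_M
    y <- ds$data$value
    if (max(abs(y)) == 0) {
      est <- c(bmax = 0, pKd_radioligand = NA_real_, ns_slope = 0)
      return(new_fit_result(est, est * NA, 0, length(y), FALSE,
                            flags = "degenerate"))
    }
    bmax0 <- max(y)
    # half-maximal concentration as a pKd starting guess
    pKd0 <- -log10(L[which.min(abs(y - bmax0 / 2))])
    specs <- list(
      parameter_spec("bmax", bmax0, lower = 0, upper = 100 * bmax0),
      parameter_spec("pKd_radioligand", pKd0, lower = 3, upper = 15),
      parameter_spec("ns_slope", 0, lower = 0, upper = 1e12,
                     fixed = !fit_ns))
    resid <- function(par) {
      p <- full_par(par, specs)
      bp <- binding_params(pKd_radioligand = p$pKd_radioligand,
                           bmax = max(p$bmax, .Machine$double.xmin),
                           ns_slope = max(p$ns_slope, 0))
      y - saturation_total_binding(L, bp)
    }
    # bmax and pKd live on very different scales; LM's internal scaling
    # copes, but jitter only the log-scale parameters
    r <- fit_global_ls(resid, specs, n_starts = n_starts, seed = seed)
    est <- r$par
    if (!fit_ns) { est <- c(est, ns_slope = 0); r$sems <- c(r$sems, ns_slope = NA) }
    new_fit_result(est, r$sems[names(est)], r$ss, length(y), r$converged)
  }

  fits <- lapply(datasets, fit_one)
  pool_replicates(fits)
}

# Pool per-replicate fit_results into a summary fit_result
# (mean +/- SEM of the replicate point estimates).
pool_replicates <- function(fits) {
  if (length(fits) == 1) {
    out <- fits[[1]]
    out$per_replicate <- fits
    return(out)
  }
  nms <- names(fits[[1]]$estimates)
  mat <- vapply(fits, function(f) f$estimates[nms], numeric(length(nms)))
  mat <- matrix(mat, nrow = length(nms),
                dimnames = list(nms, NULL))
  est <- rowMeans(mat, na.rm = TRUE)
  sem <- apply(mat, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  })
  new_fit_result(est, sem,
                 residual_ss = sum(vapply(fits, `[[`, 0, "residual_ss")),
                 n_points = sum(vapply(fits, `[[`, 0L, "n_points")),
                 converged = all(vapply(fits, `[[`, TRUE, "converged")),
                 per_replicate = fits,
                 flags = unique(unlist(lapply(fits, `[[`, "flags"))))
}

#' Global fit of the allosteric ternary complex model
#'
#' Jointly fits interaction-binding datasets (fractional specific
#' binding over an agonist x modulator concentration grid at a fixed
#' radioligand concentration) for one or more agonists against the
#' allosteric ternary complex model.  Per agonist the fit estimates the
#' agonist affinity (pKi) and the binding cooperativity (log alpha); the
#' modulator affinity (pKb) is shared across agonist datasets, and the
#' radioligand-modulator cooperativity (log alpha') is fixed at 0 by
#' default but can be freed via `spec`.
#'
#' @param datasets List of [assay_dataset()] objects
#'   (`assay_kind = "interaction_binding"`), each labelled with its
#'   agonist and replicate.
#' @param pKd_radioligand Radioligand affinity, fixed from saturation
#'   binding.
#' @param spec Optional list of [parameter_spec()] overrides (matched by
#'   name: `pKi.<agonist>`, `pKb`, `log_alpha.<agonist>`,
#'   `log_alpha_prime`).
#' @param method `"replicates"` (default) fits each replicate experiment
#'   separately and summarizes mean +/- SEM; `"pooled"` fits all data in
#'   one global regression with asymptotic SEs.
#' @param n_starts,seed Multi-start control.
#' @return A [`fit_result`][parameter_spec].
#' @export
fit_atcm_global <- function(datasets, pKd_radioligand, spec = NULL,
                            method = c("replicates", "pooled"),
                            n_starts = 5, seed = 0L) {
  method <- match.arg(method)
  stopifnot(all(vapply(datasets, function(d)
    d$assay_kind == "interaction_binding", TRUE)))
  agonists <- unique(vapply(datasets, `[[`, "", "agonist"))

  nonzero_mod <- unique(unlist(lapply(datasets, function(d)
    setdiff(unique(d$data$modulator_conc_M), 0))))
  if (length(nonzero_mod) < 3)
    warning("fewer than 3 nonzero modulator levels: ",
            "cooperativity is weakly identifiable")

  build_specs <- function(dsets) {
    specs <- list(parameter_spec("pKd_radioligand", pKd_radioligand,
                                 fixed = TRUE))
    for (ag in agonists) {
      d1 <- dsets[[which(vapply(dsets, `[[`, "", "agonist") == ag)[1]]]
      ctl <- d1$data[d1$data$modulator_conc_M == 0 &
                       d1$data$agonist_conc_M > 0, ]
      # IC50 guess from the modulator-free curve, Cheng-Prusoff corrected
      Lstar <- d1$data$radioligand_conc_M[1]
      ic50 <- ctl$agonist_conc_M[which.min(abs(ctl$value -
                                                 max(ctl$value) / 2))]
      pKi0 <- -log10(ic50 / (1 + Lstar / 10^(-pKd_radioligand)))
      if (!is.finite(pKi0)) pKi0 <- 6
      specs <- c(specs, list(
        parameter_spec(paste0("pKi.", ag), pKi0, lower = 0, upper = 14),
        parameter_spec(paste0("log_alpha.", ag), 1, lower = -5, upper = 5)))
    }
    specs <- c(specs, list(
      parameter_spec("pKb", 6, lower = 0, upper = 14),
      parameter_spec("log_alpha_prime", 0, lower = -5, upper = 5,
                     fixed = TRUE)))
    merge_specs(specs, spec)
  }

  fit_group <- function(dsets) {
    specs <- build_specs(dsets)
    resid <- function(par) {
      p <- full_par(par, specs)
      unlist(lapply(dsets, function(d) {
        bp <- binding_params(
          pKd_radioligand = p$pKd_radioligand,
          pKi_agonist = p[[paste0("pKi.", d$agonist)]],
          pKb_modulator = p$pKb,
          log_alpha = p[[paste0("log_alpha.", d$agonist)]],
          log_alpha_prime = p$log_alpha_prime)
        d$data$value - atcm_fractional_occupancy(
          d$data$radioligand_conc_M, d$data$agonist_conc_M,
          d$data$modulator_conc_M, bp)
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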