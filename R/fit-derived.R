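#' Root-sum-square propagation of standard errors
#'
#' Combines independent standard errors as the square root of the sum
#' of their squares, the propagation rule used when adding or
#' subtracting log-scale pharmacological parameters.
#'
#' @param sems Numeric vector of standard errors, all >= 0.
#' @return `sqrt(sum(sems^2))`.
#' @examples
#' propagate_sem(c(0.07, 0.10))  # 0.1221
#' @export
propagate_sem <- function(sems) {
  sems <- as.numeric(sems)
  if (any(sems < 0, na.rm = TRUE)) stop("standard errors must be >= 0")
  sqrt(sum(sems^2))
}

#' Correct operational efficacy for receptor expression
#'
#' Under the operational model tau is proportional to receptor number,
#' so efficacies measured in cell lines with different expression can be
#' put on a common scale by normalizing to the reference Bmax:
#' `log_tau_C = log_tau - log10(bmax / bmax_reference)`.
#'
#' @param log_tau log10 operational efficacy as fitted.
#' @param bmax Receptor expression of the system the efficacy was
#'   measured in (same units as `bmax_reference`, > 0).
#' @param bmax_reference Reference expression level (> 0).
#' @return Corrected log10 efficacy, log tau_C.
#' @examples
#' correct_efficacy_for_expression(1.0, 100, 1000)  # 2.0
#' @export
correct_efficacy_for_expression <- function(log_tau, bmax,
                                            bmax_reference) {
  if (any(bmax <= 0) || any(bmax_reference <= 0))
    stop("bmax values must be > 0")
  log_tau - log10(bmax / bmax_reference)
}

#' Derived allosteric parameters with propagated uncertainty
#'
#' Augments a fit with the standard derived quantities of allosteric
#' pharmacology: the occupied-state modulator affinity
#' `pKb + log alpha` (the modulator's affinity when the agonist is
#' bound, reciprocal by detailed balance), the occupied-state agonist
#' affinity `pKi + log alpha`, the fold cooperativity `10^log alpha`,
#' and the efficacy-modulation component
#' `log beta = log alphabeta - log alpha`.  SEMs of log-scale sums are
#' propagated with [propagate_sem()]; the fold cooperativity SEM uses
#' the delta method.
#'
#' @param fit A [`fit_result`][parameter_spec] containing some of
#'   `pKb`, `pKi.<agonist>`, `log_alpha.<agonist>`,
#'   `log_alphabeta.<agonist>`.
#' @param log_alpha Optional named vector `log_alpha.<agonist>` when the
#'   fit itself (e.g. a functional fit) does not estimate binding
#'   cooperativity; `log_alpha_sem` its SEMs in the same order.
#' @param log_alpha_sem See `log_alpha`.
#' @return The fit with its `derived` field populated; each entry is
#'   `c(value, sem)`.
#' @export
derived_parameters <- function(fit, log_alpha = NULL,
                               log_alpha_sem = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  est <- fit$estimates
  sem <- fit$sems
  g <- function(nm) if (nm %in% names(est)) est[[nm]] else NULL
  gs <- function(nm) {
    v <- if (nm %in% names(sem)) sem[[nm]] else NA_real_
    if (is.na(v)) 0 else v
  }
  alpha_of <- function(ag) {
    nm <- paste0("log_alpha.", ag)
    if (!is.null(log_alpha) && nm %in% names(log_alpha))
      return(c(log_alpha[[nm]],
               if (!is.null(log_alpha_sem) && nm %in% names(log_alpha_sem))
                 log_alpha_sem[[nm]] else 0))
    if (nm %in% names(est)) return(c(est[[nm]], gs(nm)))
    NULL
  }

  agonists <- unique(sub("^(pKi|log_alpha|log_alphabeta|log_tau_A)\\.",
                         "",
                         grep("^(pKi|log_alpha|log_alphabeta|log_tau_A)\\.",
                              names(c(est, log_alpha)), value = TRUE)))
  der <- list()
  for (ag in agonists) {
    a <- alpha_of(ag)
    if (!is.null(a)) {
      if (!is.null(g("pKb")))
        der[[paste0("pKb_occupied.", ag)]] <-
          c(g("pKb") + a[1], propagate_sem(c(gs("pKb"), a[2])))
      ki <- g(paste0("pKi.", ag))
      if (!is.null(ki))
        der[[paste0("pKi_occupied.", ag)]] <-
          c(ki + a[1], propagate_sem(c(gs(paste0("pKi.", ag)), a[2])))
      der[[paste0("fold_alpha.", ag)]] <-
        c(10^a[1], log(10) * 10^a[1] * a[2])
      ab <- g(paste0("log_alphabeta.", ag))
      if (!is.null(ab))
        der[[paste0("log_beta.", ag)]] <-
          c(ab - a[1],
            propagate_sem(c(gs(paste0("log_alphabeta.", ag)), a[2])))
    }
  }
  fit$derived <- der
  fit
}

#' Summarize replicate fits as mean +/- SEM
#'
#' @param fits List of [`fit_result`][parameter_spec] objects with the
#'   same parameter names (one per independent experiment).
#' @return Data frame with columns `parameter`, `mean`, `sem`, `n` and
#'   `formatted` (`"mean +/- SEM (n)"`); with a single replicate the SEM
#'   is reported as `NA`.
#' @examples
#' # three replicates of a single-parameter fit
#' @export
summarize_replicates <- function(fits) {
  stopifnot(length(fits) >= 1)
  nms <- names(fits[[1]]$estimates)
  for (f in fits)
    if (!identical(sort(names(f$estimates)), sort(nms)))
      stop("replicate fits must share parameter names")
  rows <- lapply(nms, function(nm) {
    v <- vapply(fits, function(f) f$estimates[[nm]], 0)
    v <- v[is.finite(v)]
    n <- length(v)
    m <- mean(v)
    s <- if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_
    data.frame(parameter = nm, mean = m, sem = s, n = n,
               formatted = format_pm(m, s, n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format "mean +/- SEM (n)" table cells
#'
#' Values are rounded to 2 decimals (round-half-even, R's [round()]);
#' missing values render as `"N.D."`.
#'
#' @param mean,sem,n Summary values.
#' @param digits Decimal places (default 2).
#' @return Character scalar.
#' @export
format_pm <- function(mean, sem, n = NA, digits = 2) {
  if (!is.finite(mean)) return("N.D.")
  fm <- formatC(round(mean, digits), format = "f", digits = digits)
  fs <- if (is.finite(sem))
    formatC(round(sem, digits), format = "f", digits = digits) else NA
  out <- if (is.na(fs)) fm else paste0(fm, " ± ", fs)
  if (is.finite(n)) paste0(out, " (", n, ")") else out
}
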