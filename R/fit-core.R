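#' Parameter specification for global fits
#'
#' Describes one free, fixed or shared parameter of a global nonlinear
#' least-squares fit.  Parameters with the same `name` across datasets
#' are one free variable (sharing is by name); `fixed = TRUE` pins the
#' parameter at `initial`.
#'
#' @param name Parameter name (e.g. `"pKb"`, `"log_alpha.ACh"`).
#' @param initial Starting value; must lie within `[lower, upper]`.
#' @param lower,upper Box bounds (default unbounded).
#' @param fixed If `TRUE` the parameter never moves.
#' @return An object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, initial, lower = -Inf, upper = Inf,
                           fixed = FALSE) {
  if (!(lower <= initial && initial <= upper))
    stop("initial must satisfy lower <= initial <= upper for ", name)
  structure(list(name = name, initial = initial, lower = lower,
                 upper = upper, fixed = fixed),
            class = "parameter_spec")
}

#' @export
print.parameter_spec <- function(x, ...) {
  cat(sprintf("<parameter_spec> %s = %g [%g, %g]%s\n", x$name, x$initial,
              x$lower, x$upper, if (x$fixed) " (fixed)" else ""))
  invisible(x)
}

# Merge user-supplied specs (a list of parameter_spec) over defaults,
# matched by name.
merge_specs <- function(defaults, overrides) {
  if (is.null(overrides)) return(defaults)
  nm <- vapply(defaults, `[[`, "", "name")
  for (ov in overrides) {
    stopifnot(inherits(ov, "parameter_spec"))
    i <- match(ov$name, nm)
    if (is.na(i)) defaults[[length(defaults) + 1]] <- ov
    else defaults[[i]] <- ov
  }
  defaults
}

#' One assay experiment
#'
#' Container for a single independent experiment: a concentration grid
#' plus the measured values.
#'
#' @param data Data frame with columns `agonist_conc_M`,
#'   `modulator_conc_M`, `value` and, for binding assays,
#'   `radioligand_conc_M`.
#' @param assay_kind One of `"saturation"`, `"interaction_binding"`,
#'   `"functional"`.
#' @param agonist Label of the orthosteric agonist in this experiment.
#' @param modulator Label of the allosteric modulator (or `NA`).
#' @param replicate Integer experiment index.
#' @param normalization Free-text description of how values were scaled.
#' @return An object of class `assay_dataset`.
#' @export
assay_dataset <- function(data, assay_kind, agonist = NA_character_,
                          modulator = NA_character_, replicate = 1L,
                          normalization = "") {
  assay_kind <- match.arg(assay_kind,
                          c("saturation", "interaction_binding",
                            "functional"))
  data <- as.data.frame(data)
  need <- if (assay_kind == "saturation") {
    c("radioligand_conc_M", "value")
  } else if (assay_kind == "interaction_binding") {
    c("agonist_conc_M", "modulator_conc_M", "radioligand_conc_M", "value")
  } else {
    c("agonist_conc_M", "modulator_conc_M", "value")
  }
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(data$value))) stop("values must be finite")
  structure(list(data = data, assay_kind = assay_kind,
                 agonist = agonist, modulator = modulator,
                 replicate = as.integer(replicate),
                 normalization = normalization),
            class = "assay_dataset")
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat(sprintf("<assay_dataset> %s, agonist=%s, modulator=%s, replicate %d, %d points\n",
              x$assay_kind, x$agonist, x$modulator, x$replicate,
              nrow(x$data)))
  invisible(x)
}

new_fit_result <- function(estimates, sems, residual_ss, n_points,
                           converged, per_replicate = NULL,
                           derived = NULL, flags = character()) {
  structure(list(estimates = estimates, sems = sems,
                 residual_ss = residual_ss, n_points = n_points,
                 converged = converged, per_replicate = per_replicate,
                 derived = derived, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, digits = 3, ...) {
  cat(sprintf("<fit_result> %s, SS = %.6g over %d points\n",
              if (x$converged) "converged" else "NOT CONVERGED",
              x$residual_ss, x$n_points))
  est <- x$estimates
  sem <- x$sems[names(est)]
  for (nm in names(est)) {
    if (is.finite(sem[nm]))
      cat(sprintf("  %-24s %8.4g +/- %.3g\n", nm, est[nm], sem[nm]))
    else cat(sprintf("  %-24s %8.4g\n", nm, est[nm]))
  }
  if (length(x$derived)) {
    cat("  derived:\n")
    for (nm in names(x$derived))
      cat(sprintf("  %-24s %8.4g +/- %.3g\n", nm, x$derived[[nm]][1],
                  x$derived[[nm]][2]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Core bounded multi-start Levenberg-Marquardt engine shared by all the
# global fitters.
#
# residual_fn(par): named free-parameter vector -> residual vector
# (observed - predicted, concatenated over datasets).  Fixed parameters
# are closed over by residual_fn's constructor.
fit_global_ls <- function(residual_fn, specs, n_starts = 5,
                          jitter_sd = 1, seed = 0L) {
  fixed <- vapply(specs, `[[`, TRUE, "fixed")
  free <- specs[!fixed]
  if (!length(free)) stop("no free parameters")
  p0 <- vapply(free, `[[`, 0, "initial")
  names(p0) <- vapply(free, `[[`, "", "name")
  lo <- vapply(free, `[[`, 0, "lower")
  hi <- vapply(free, `[[`, 0, "upper")

  starts <- list(p0)
  if (n_starts > 1) {
    rng <- local({ set.seed(seed); lapply(seq_len(n_starts - 1), function(i)
      stats::runif(length(p0), -jitter_sd, jitter_sd)) })
    for (d in rng) starts[[length(starts) + 1]] <- pmin(pmax(p0 + d, lo), hi)
  }

  best <- NULL
  ctl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                    maxiter = 500)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lo, upper = hi,
                         fn = residual_fn, control = ctl),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- fit$deviance
    if (is.null(best) || ss < best$ss - 1e-12 ||
        (abs(ss - best$ss) <= 1e-12 &&
         sum(fit$par^2) < sum(best$par^2))) {
      best <- list(par = fit$par, ss = ss, info = fit$info,
                   niter = fit$niter)
    }
  }
  if (is.null(best))
    return(list(par = p0, ss = Inf, converged = FALSE, sems = p0 * NA))

  converged <- best$info %in% 1:4 && all(is.finite(best$par))

  # asymptotic SEs from a central-difference Jacobian at the optimum
  sems <- rep(NA_real_, length(p0))
  names(sems) <- names(p0)
  r0 <- residual_fn(best$par)
  npar <- length(best$par)
  dof <- length(r0) - npar
  if (dof > 0 && converged) {
    J <- matrix(0, length(r0), npar)
    for (j in seq_len(npar)) {
      h <- max(1e-6, 1e-6 * abs(best$par[j]))
      # one-sided steps when a bound is closer than h
      pp <- best$par; pp[j] <- min(pp[j] + h, hi[j])
      pm <- best$par; pm[j] <- max(pm[j] - h, lo[j])
      if (pp[j] > pm[j])
        J[, j] <- (residual_fn(pp) - residual_fn(pm)) / (pp[j] - pm[j])
    }
    sigma2 <- best$ss / dof
    V <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
    if (!is.null(V)) sems <- sqrt(pmax(diag(V), 0))
    names(sems) <- names(p0)
  }

  list(par = best$par, ss = best$ss, converged = converged, sems = sems)
}

# Assemble the full named parameter list (free + fixed) for prediction.
full_par <- function(free_par, specs) {
  out <- lapply(specs, `[[`, "initial")
  names(out) <- vapply(specs, `[[`, "", "name")
  out[names(free_par)] <- as.list(free_par)
  out
}
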