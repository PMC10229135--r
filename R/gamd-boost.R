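# Boltzmann constant in kcal/mol/K
KB_KCAL <- 0.0019872041

#' Summary statistics of a potential-energy series
#'
#' Running minimum, maximum, mean and standard deviation of sampled
#' potential energies, the inputs to the boost-parameter equations.
#'
#' @param v_samples Numeric vector of potential energies (kcal/mol),
#'   length >= 2.
#' @return List with `vmin`, `vmax`, `vavg`, `sigma_v` (sample SD).
#' @export
estimate_potential_statistics <- function(v_samples) {
  v_samples <- as.numeric(v_samples)
  if (length(v_samples) < 2) stop("need at least 2 potential samples")
  list(vmin = min(v_samples), vmax = max(v_samples),
       vavg = mean(v_samples), sigma_v = stats::sd(v_samples))
}

#' Harmonic boost parameters from potential statistics
#'
#' Determines the threshold energy E and force constant k of the
#' Gaussian-accelerated harmonic boost from the sampled potential
#' statistics, under either threshold choice:
#'
#' * lower bound: `E = Vmax`,
#'   `k0 = min(1, (sigma0/sigma_V) * (Vmax - Vmin)/(Vmax - Vavg))`;
#' * upper bound: `k0'' = (1 - sigma0/sigma_V) * (Vmax - Vmin)/(Vavg - Vmin)`,
#'   accepted iff `0 < k0'' <= 1` (otherwise the lower-bound formula is
#'   used), with `E = Vmin + 1/k`.
#'
#' In both cases `k = k0 / (Vmax - Vmin)`, which guarantees the
#' smoothing constraint `Vmax <= E <= Vmin + 1/k`.
#'
#' @param stats Output of [estimate_potential_statistics()].
#' @param sigma0 Upper limit on the boost-potential SD (kcal/mol),
#'   default 6.0.
#' @param bound_mode `"lower"` or `"upper"` threshold-energy choice.
#' @return Object of class `boost_parameters`: `E`, `k`, `k0`, the
#'   input statistics, the mode actually used, and `flags`.
#' @examples
#' st <- list(vmin = 0, vmax = 10, vavg = 6, sigma_v = 2)
#' compute_boost(st, sigma0 = 1, bound_mode = "lower")  # k0 = 1, E = 10
#' @export
compute_boost <- function(stats, sigma0 = 6, bound_mode = c("lower",
                                                            "upper")) {
  bound_mode <- match.arg(bound_mode)
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  vmin <- stats$vmin; vmax <- stats$vmax
  vavg <- stats$vavg; sigma_v <- stats$sigma_v
  if (sigma_v < 0) stop("sigma_v must be >= 0")
  flags <- character()

  if (vmax <= vmin) {
    return(structure(list(E = vmax, k = 0, k0 = 0, vmin = vmin,
                          vmax = vmax, vavg = vavg, sigma_v = sigma_v,
                          mode = "disabled",
                          flags = "degenerate: vmax == vmin"),
                     class = "boost_parameters"))
  }

  k0_lower <- if (sigma_v == 0) 1 else
    min(1, (sigma0 / sigma_v) * (vmax - vmin) / (vmax - vavg))
  mode <- "lower"
  k0 <- k0_lower
  if (bound_mode == "upper") {
    if (sigma_v == 0) {
      flags <- c(flags, "sigma_v = 0: fell back to lower bound")
    } else {
      k0pp <- (1 - sigma0 / sigma_v) * (vmax - vmin) / (vavg - vmin)
      if (is.finite(k0pp) && k0pp > 0 && k0pp <= 1) {
        k0 <- k0pp
        mode <- "upper"
      } else {
        flags <- c(flags, "k0'' outside (0, 1]: fell back to lower bound")
      }
    }
  }
  k <- k0 / (vmax - vmin)
  E <- if (mode == "upper") vmin + 1 / k else vmax
  stopifnot(vmax <= E + 1e-9, E <= vmin + 1 / k + 1e-9)
  structure(list(E = E, k = k, k0 = k0, vmin = vmin, vmax = vmax,
                 vavg = vavg, sigma_v = sigma_v, mode = mode,
                 flags = flags),
            class = "boost_parameters")
}

#' @export
print.boost_parameters <- function(x, ...) {
  cat(sprintf("<boost_parameters> mode=%s E=%.4g k=%.4g k0=%.4g\n",
              x$mode, x$E, x$k, x$k0))
  cat(sprintf("  V stats: min=%.4g max=%.4g avg=%.4g sd=%.4g\n",
              x$vmin, x$vmax, x$vavg, x$sigma_v))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Harmonic boost potential
#'
#' `delta_v = 0.5 * k * (E - v)^2` when `v < E`, and 0 otherwise.
#' Always >= 0; preserves the order of potential values and shrinks
#' their gaps on the boosted surface.
#'
#' @param v Potential energies (kcal/mol), vectorized.
#' @param boost A `boost_parameters` object.
#' @return Boost energies (kcal/mol).
#' @export
delta_v <- function(v, boost) {
  stopifnot(inherits(boost, "boost_parameters"))
  ifelse(v < boost$E, 0.5 * boost$k * (boost$E - v)^2, 0)
}
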