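#' Total radioligand binding in a saturation assay
#'
#' Hyperbolic one-site saturation binding plus a linear nonspecific
#' component: `bmax * L / (L + Kd) + ns_slope * L` with
#' `Kd = 10^-pKd_radioligand`.
#'
#' @param L Molar radioligand concentration(s), >= 0.
#' @param params A [binding_params()] object.
#' @return Total binding in the units of `bmax`.
#' @examples
#' bp <- binding_params(pKd_radioligand = 9, bmax = 1000)
#' saturation_total_binding(1e-9, bp)  # half-saturation -> 500
#' @export
saturation_total_binding <- function(L, params) {
  stopifnot(inherits(params, "binding_params"))
  L <- as.numeric(L)
  if (any(L < 0)) stop("radioligand concentration must be >= 0")
  Kd <- 10^(-params$pKd_radioligand)
  params$bmax * L / (L + Kd) + params$ns_slope * L
}

#' Fractional radioligand occupancy under the allosteric ternary complex model
#'
#' Equilibrium fraction of receptors occupied by the radioligand in the
#' simultaneous presence of an orthosteric competitor (agonist) and an
#' allosteric modulator.  The modulator changes the apparent affinity of
#' both orthosteric ligands through the cooperativities alpha
#' (agonist-modulator) and alpha' (radioligand-modulator):
#'
#' \deqn{\rho = \frac{L^*}{L^* + K_{A^*}\,
#'   \frac{1 + I/K_I + B/K_B + \alpha I B/(K_I K_B)}
#'        {1 + \alpha' B/K_B}}}
#'
#' @param Lstar Molar radioligand concentration(s).
#' @param I Molar agonist (competitor) concentration(s).
#' @param B Molar modulator concentration(s).
#' @param params A [binding_params()] object supplying pKd_radioligand
#'   (radioligand), pKi_agonist, pKb_modulator, log_alpha and
#'   log_alpha_prime.
#' @return Fractional occupancy in `[0, 1]`; vectorized over the longest
#'   of `Lstar`, `I`, `B`.
#' @examples
#' bp <- binding_params(pKd_radioligand = 9.76, pKi_agonist = 4.50,
#'                      pKb_modulator = 5.65, log_alpha = 2.59)
#' atcm_fractional_occupancy(10^-9.76, 0, 0, bp)  # 0.5
#' @export
atcm_fractional_occupancy <- function(Lstar, I, B, params) {
  stopifnot(inherits(params, "binding_params"))
  n <- max(length(Lstar), length(I), length(B))
  Lstar <- rep_len(as.numeric(Lstar), n)
  I <- rep_len(as.numeric(I), n)
  B <- rep_len(as.numeric(B), n)
  if (any(Lstar < 0) || any(I < 0) || any(B < 0))
    stop("concentrations must be >= 0")
  for (nm in c("pKd_radioligand", "pKi_agonist", "pKb_modulator",
               "log_alpha", "log_alpha_prime"))
    if (!is.finite(params[[nm]])) stop("non-finite parameter: ", nm)
  Kast <- 10^(-params$pKd_radioligand)
  Ki <- 10^(-params$pKi_agonist)
  Kb <- 10^(-params$pKb_modulator)
  alpha <- 10^params$log_alpha
  alphap <- 10^params$log_alpha_prime
  num <- 1 + I / Ki + B / Kb + alpha * I * B / (Ki * Kb)
  den <- 1 + alphap * B / Kb
  Lstar / (Lstar + Kast * num / den)
}

#' Black-Leff operational model of agonism
#'
#' Response = basal + (Em - basal) * tau^n A^n / ((A + K_A)^n + tau^n A^n),
#' with tau = 10^log_tau_A and K_A = 10^-pKa_agonist.
#'
#' @param A Molar agonist concentration(s), >= 0.
#' @param params A [functional_params()] object.
#' @return Response in the units of `em` (vectorized over `A`).
#' @examples
#' fp <- functional_params(pKa_agonist = 6, log_tau_A = 1)
#' operational_agonism_response(1e-6, fp)  # 100 * 10 / 12
#' @export
operational_agonism_response <- function(A, params) {
  stopifnot(inherits(params, "functional_params"))
  A <- as.numeric(A)
  if (any(A < 0)) stop("agonist concentration must be >= 0")
  if (params$n_slope <= 0) stop("n_slope must be > 0")
  tau <- 10^params$log_tau_A
  Ka <- 10^(-params$pKa_agonist)
  n <- params$n_slope
  num <- (tau * A)^n
  den <- (A + Ka)^n + num
  params$basal + (params$em - params$basal) * num / den
}

#' Operational model of allosterism and agonism
#'
#' Combined orthosteric/allosteric operational model (the
#' Leach-Sexton-Christopoulos form used by standard curve-fitting
#' templates):
#' \deqn{E = basal + (E_m - basal)\frac{N^n}{D^n + N^n}} with
#' \deqn{N = \tau_A A (K_B + \alpha\beta B) + \tau_B B K_A}
#' \deqn{D = A K_B + K_A K_B + K_A B + \alpha A B}
#' It reduces exactly to [operational_agonism_response()] at `B = 0`, and
#' to the modulator-alone agonism curve at `A = 0`.
#'
#' @param A Molar agonist concentration(s).
#' @param B Molar modulator concentration(s).
#' @param params A [functional_params()] object.
#' @return Response in the units of `em`, vectorized over the longer of
#'   `A` and `B`.
#' @examples
#' fp <- functional_params(pKa_agonist = 6, pKb_modulator = 6,
#'                         log_tau_A = 1, log_tau_B = 0,
#'                         log_alphabeta = 1, log_alpha = 1)
#' operational_allosterism_response(1e-6, 1e-6, fp)
#' @export
operational_allosterism_response <- function(A, B, params) {
  stopifnot(inherits(params, "functional_params"))
  n <- max(length(A), length(B))
  A <- rep_len(as.numeric(A), n)
  B <- rep_len(as.numeric(B), n)
  if (any(A < 0) || any(B < 0)) stop("concentrations must be >= 0")
  if (params$n_slope <= 0) stop("n_slope must be > 0")
  tauA <- 10^params$log_tau_A
  tauB <- 10^params$log_tau_B          # -Inf -> 0, a silent modulator
  Ka <- 10^(-params$pKa_agonist)
  Kb <- 10^(-params$pKb_modulator)
  ab <- 10^params$log_alphabeta
  alpha <- 10^params$log_alpha
  ns <- params$n_slope
  N <- tauA * A * (Kb + ab * B) + tauB * B * Ka
  D <- A * Kb + Ka * Kb + Ka * B + alpha * A * B
  num <- N^ns
  resp <- params$basal + (params$em - params$basal) * num / (D^ns + num)
  # N = 0 (e.g. A = B = 0, or silent ligands) must give basal, not NaN
  resp[N == 0] <- params$basal
  resp
}

#' Baseline-normalized BRET ratio with area-under-curve summary
#'
#' Processes a BRET kinetic trace the way G-protein activation assays
#' are summarized: the acceptor/donor emission ratio is computed per time
#' point, normalized to its mean over the pre-addition baseline window,
#' corrected by the identically processed vehicle trace, and integrated
#' by the trapezoid rule over the post-addition window.
#'
#' @param times Time points (minutes), strictly increasing, length >= 2.
#' @param acceptor,donor Emission intensities of the treated wells at
#'   `times` (e.g. 515/30 nm and 410/80 nm channels).
#' @param vehicle_acceptor,vehicle_donor Matched vehicle-well emissions
#'   on the same time grid.
#' @param baseline_window Length-2 numeric, `[start, end]` of the
#'   baseline period; times > `baseline_window[2]` form the
#'   post-addition integration window.
#' @return A list with `ratio_corrected` (per time point) and `auc`
#'   (ratio x time units over the post-addition window).
#' @export
bret_ratio_auc <- function(times, acceptor, donor,
                           vehicle_acceptor, vehicle_donor,
                           baseline_window) {
  times <- as.numeric(times)
  if (length(times) < 2) stop("need at least 2 time points")
  lens <- c(length(acceptor), length(donor),
            length(vehicle_acceptor), length(vehicle_donor))
  if (any(lens != length(times)))
    stop("all traces must share the time grid")
  if (any(donor == 0) || any(vehicle_donor == 0))
    stop("zero donor emission")
  base <- times >= baseline_window[1] & times <= baseline_window[2]
  if (!any(base)) stop("baseline window contains no time points")
  norm_ratio <- function(acc, don) {
    r <- acc / don
    r / mean(r[base])
  }
  corrected <- norm_ratio(acceptor, donor) -
    norm_ratio(vehicle_acceptor, vehicle_donor)
  post <- times > baseline_window[2]
  if (sum(post) < 2) stop("post-addition window needs >= 2 time points")
  tp <- times[post]
  yp <- corrected[post]
  auc <- sum(diff(tp) * (head(yp, -1) + tail(yp, -1)) / 2)
  list(ratio_corrected = corrected, auc = auc)
}
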