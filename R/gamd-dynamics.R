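#' Settings for the Langevin / Gaussian-accelerated dynamics engine
#'
#' The engine works in reduced units: energies in kcal/mol, unit
#' particle mass, coordinates in arbitrary length units, and a
#' configurable time step.  Only the boost and reweighting mathematics
#' are claimed faithful to production molecular-dynamics protocols; the
#' integrator itself is a desk-scale stand-in.
#'
#' @param sigma0 Upper limit on the boost-potential SD per boosted term
#'   (kcal/mol), default 6.0.
#' @param bound_mode Threshold-energy choice, `"lower"` or `"upper"`.
#' @param temperature Kelvin, default 300.
#' @param friction Langevin friction (1/time unit).
#' @param dt Integration time step (time units), default 1e-3.
#' @param n_equil_cmd Conventional-dynamics steps used to collect the
#'   potential statistics.
#' @param n_equil_boost Equilibration steps with the boost applied and
#'   parameters updated every `update_interval` steps.
#' @param n_prod Production steps with frozen boost parameters.
#' @param update_interval Boost-update cadence during equilibration.
#' @param record_stride Record every this-many production steps.
#' @param seed Integer seed; the statistics, equilibration and
#'   production stages use `seed`, `seed + 1` and `seed + 2` so a
#'   production segment is reproducible in isolation.
#' @param dual_boost Apply an independent boost to the surface's first
#'   additive term in addition to the total-potential boost (requires a
#'   surface exposing a `terms` decomposition).
#' @param k0_override If non-`NULL`, force k0 to this value instead of
#'   the automatically determined one (0 disables the boost entirely).
#' @param x0,v0 Optional initial position / velocity vectors.
#' @return Object of class `gamd_settings`.
#' @export
gamd_settings <- function(sigma0 = 6, bound_mode = "lower",
                          temperature = 300, friction = 1, dt = 1e-3,
                          n_equil_cmd = 10000L, n_equil_boost = 20000L,
                          n_prod = 100000L, update_interval = 10000L,
                          record_stride = 1L, seed = 0L,
                          dual_boost = FALSE, k0_override = NULL,
                          x0 = NULL, v0 = NULL) {
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (n_prod <= 0) stop("n_prod must be > 0")
  structure(list(sigma0 = sigma0, bound_mode = bound_mode,
                 temperature = temperature, friction = friction,
                 dt = dt, n_equil_cmd = as.integer(n_equil_cmd),
                 n_equil_boost = as.integer(n_equil_boost),
                 n_prod = as.integer(n_prod),
                 update_interval = as.integer(update_interval),
                 record_stride = as.integer(record_stride),
                 seed = as.integer(seed), dual_boost = dual_boost,
                 k0_override = k0_override, x0 = x0, v0 = v0),
            class = "gamd_settings")
}

# One Langevin (BAOAB) run segment.  `boosts` is NULL (plain dynamics)
# or list(total = <boost_parameters>, first = <boost_parameters or NULL>,
# term1 = <potential_surface or NULL>).  RNG state is whatever the
# caller set.  Returns recorded frames and the final phase-space state.
langevin_run <- function(potential, n_steps, state, settings,
                         boosts = NULL, record_stride = 1L,
                         collect_v = FALSE) {
  dim <- potential$dimensionality
  dt <- settings$dt
  hdt <- dt / 2
  kbt <- KB_KCAL * settings$temperature
  c1 <- exp(-settings$friction * dt)
  c2 <- sqrt((1 - c1^2) * kbt)
  energy <- potential$energy
  gradient <- potential$gradient

  bt <- boosts$total
  b1 <- boosts$first
  t1 <- boosts$term1
  use_bt <- !is.null(bt) && bt$k0 > 0
  use_b1 <- !is.null(b1) && b1$k0 > 0 && !is.null(t1)

  eval_point <- function(x) {
    V <- energy(x)
    g <- gradient(x)
    dv <- 0
    if (use_bt && V < bt$E) {
      g <- g * (1 - bt$k * (bt$E - V))
      dv <- dv + 0.5 * bt$k * (bt$E - V)^2
    }
    if (use_b1) {
      V1 <- t1$energy(x)
      if (V1 < b1$E) {
        g <- g - t1$gradient(x) * (b1$k * (b1$E - V1))
        dv <- dv + 0.5 * b1$k * (b1$E - V1)^2
      }
    }
    list(V = V, f = -g, dv = dv)
  }

  noise <- matrix(stats::rnorm(n_steps * dim), n_steps, dim)
  x <- state$x
  v <- state$v
  ep <- eval_point(x)
  n_rec <- n_steps %/% record_stride
  coords <- matrix(NA_real_, n_rec, dim)
  pot_v <- numeric(n_rec)
  boost_v <- numeric(n_rec)
  vfull <- if (collect_v) numeric(n_steps) else NULL
  irec <- 0L
  for (s in seq_len(n_steps)) {
    v <- v + hdt * ep$f
    x <- x + hdt * v
    v <- c1 * v + c2 * noise[s, ]
    x <- x + hdt * v
    ep <- eval_point(x)
    v <- v + hdt * ep$f
    if (!is.finite(ep$V) || ep$V > 1e3)
      stop("energy diverged (", format(ep$V),
           " kcal/mol): reduce dt or friction")
    if (collect_v) vfull[s] <- ep$V
    if (s %% record_stride == 0L) {
      irec <- irec + 1L
      coords[irec, ] <- x
      pot_v[irec] <- ep$V
      boost_v[irec] <- ep$dv
    }
  }
  list(coords = coords, potential = pot_v, boost = boost_v,
       v_samples = vfull, state = list(x = x, v = v))
}

default_state <- function(potential, settings) {
  dim <- potential$dimensionality
  x <- settings$x0
  if (is.null(x)) {
    x <- rep(0, dim)
    if (!is.null(potential$minima)) x[1] <- potential$minima[1]
  }
  v <- settings$v0
  if (is.null(v))
    v <- stats::rnorm(dim) * sqrt(KB_KCAL * settings$temperature)
  list(x = x, v = v)
}

new_boosted_trajectory <- function(seg, settings) {
  n <- nrow(seg$coords)
  structure(list(coords = seg$coords, potential = seg$potential,
                 boost = seg$boost,
                 frame_times = seq_len(n) * settings$dt *
                   settings$record_stride,
                 final_state = seg$state),
            class = "boosted_trajectory")
}

#' @export
print.boosted_trajectory <- function(x, ...) {
  cat(sprintf("<boosted_trajectory> %d frames x %d dim; max boost %.3g kcal/mol\n",
              nrow(x$coords), ncol(x$coords), max(x$boost)))
  invisible(x)
}

#' Conventional Langevin dynamics on a toy surface
#'
#' BAOAB-splitting Langevin integration sampling the canonical ensemble
#' of the surface at the requested temperature.  The boost channel of
#' the returned trajectory is identically zero.
#'
#' @param potential A [toy_potential()] surface.
#' @param settings A [gamd_settings()] object; `n_prod` steps are run
#'   from `x0`/`v0` (defaults: the first minimum / a Maxwell draw) with
#'   `set.seed(seed)`.
#' @return A `boosted_trajectory`.
#' @export
run_cmd <- function(potential, settings) {
  stopifnot(inherits(potential, "potential_surface"),
            inherits(settings, "gamd_settings"))
  set.seed(settings$seed)
  state <- default_state(potential, settings)
  seg <- langevin_run(potential, settings$n_prod, state, settings,
                      boosts = NULL,
                      record_stride = settings$record_stride)
  new_boosted_trajectory(seg, settings)
}

#' Gaussian-accelerated dynamics on a toy surface
#'
#' Three-stage protocol: (1) conventional dynamics collecting potential
#' statistics; (2) boosted equilibration with the boost parameters
#' re-estimated every `update_interval` steps from the accumulated
#' statistics; (3) production with frozen boost, recording the
#' potential and boost energy per frame.  On the boosted surface the
#' force is the plain force scaled by `1 - k (E - V)` below threshold
#' (a factor in `[0, 1]` by the E, k invariant).
#'
#' With `dual_boost = TRUE` and a decomposable surface, an independent
#' boost is applied to the first additive term and to the total
#' potential; the recorded boost is their sum.
#'
#' @param potential A [toy_potential()] surface.
#' @param settings A [gamd_settings()].
#' @return A list of class `gamd_run`: `boost` (total-potential boost
#'   parameters), `boost_first` (first-term boost or `NULL`),
#'   `trajectory` (production `boosted_trajectory`), and
#'   `production_start` (phase-space state at production start, so that
#'   a production segment can be reproduced in isolation with
#'   [run_cmd()] at seed `seed + 2`).
#' @export
run_gamd <- function(potential, settings) {
  stopifnot(inherits(potential, "potential_surface"),
            inherits(settings, "gamd_settings"))
  if (settings$n_equil_cmd <= 0)
    stop("n_equil_cmd must be > 0 to collect potential statistics")
  if (settings$dual_boost && is.null(potential$terms))
    stop("dual_boost requires a surface with a two-term decomposition")

  term1 <- if (settings$dual_boost) potential$terms[[1]] else NULL

  # stage 1: conventional dynamics, potential statistics
  set.seed(settings$seed)
  state <- default_state(potential, settings)
  seg <- langevin_run(potential, settings$n_equil_cmd, state, settings,
                      boosts = NULL, record_stride = 1L,
                      collect_v = TRUE)
  v_hist <- seg$v_samples
  v1_hist <- if (settings$dual_boost)
    apply(seg$coords, 1, term1$energy) else NULL
  state <- seg$state

  make_boost <- function(vh) {
    b <- compute_boost(estimate_potential_statistics(vh),
                       sigma0 = settings$sigma0,
                       bound_mode = settings$bound_mode)
    if (!is.null(settings$k0_override)) {
      b$k0 <- settings$k0_override
      b$k <- if (b$vmax > b$vmin) b$k0 / (b$vmax - b$vmin) else 0
      b$E <- if (b$mode == "upper" && b$k > 0) b$vmin + 1 / b$k else b$vmax
    }
    b
  }
  bt <- make_boost(v_hist)
  b1 <- if (settings$dual_boost) make_boost(v1_hist) else NULL

  # stage 2: boosted equilibration with periodic parameter updates
  set.seed(settings$seed + 1L)
  remaining <- settings$n_equil_boost
  while (remaining > 0) {
    chunk <- min(settings$update_interval, remaining)
    seg <- langevin_run(potential, chunk, state, settings,
                        boosts = list(total = bt, first = b1,
                                      term1 = term1),
                        record_stride = 1L, collect_v = TRUE)
    v_hist <- c(v_hist, seg$v_samples)
    if (settings$dual_boost)
      v1_hist <- c(v1_hist, apply(seg$coords, 1, term1$energy))
    state <- seg$state
    bt <- make_boost(v_hist)
    if (settings$dual_boost) b1 <- make_boost(v1_hist)
    remaining <- remaining - chunk
  }

  # stage 3: production with frozen boost
  production_start <- state
  set.seed(settings$seed + 2L)
  seg <- langevin_run(potential, settings$n_prod, state, settings,
                      boosts = list(total = bt, first = b1,
                                    term1 = term1),
                      record_stride = settings$record_stride)
  structure(list(boost = bt, boost_first = b1,
                 trajectory = new_boosted_trajectory(seg, settings),
                 production_start = production_start),
            class = "gamd_run")
}

#' @export
print.gamd_run <- function(x, ...) {
  print(x$boost)
  print(x$trajectory)
  invisible(x)
}
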