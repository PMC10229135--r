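#' Noise model for synthetic assay data
#'
#' @param kind `"gaussian_additive"` or `"gaussian_multiplicative"`.
#' @param sd Noise SD, in response units (additive) or as a fraction of
#'   the signal (multiplicative); >= 0.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(kind = c("gaussian_additive",
                                 "gaussian_multiplicative"),
                        sd = 0.03) {
  kind <- match.arg(kind)
  if (sd < 0) stop("sd must be >= 0")
  structure(list(kind = kind, sd = sd), class = "noise_model")
}

apply_noise <- function(values, noise) {
  if (noise$sd == 0) return(values)
  eps <- stats::rnorm(length(values), 0, noise$sd)
  switch(noise$kind,
         gaussian_additive = values + eps,
         gaussian_multiplicative = values * (1 + eps))
}

#' Concentration design for an interaction experiment
#'
#' Builds the standard interaction design: the radioligand at its
#' equilibrium dissociation constant, agonist half-log dilutions
#' spanning pK +/- 3, and a modulator half-log series spanning
#' pKb - 1 to pKb + 3 plus a vehicle (0) column.
#'
#' @param truth A [binding_params()] or [functional_params()] object
#'   supplying the affinities the series are centered on.
#' @param n_agonist Number of agonist concentrations (>= 6); the series
#'   is geometric with ratio `10^0.5` starting at `10^-(pK + 3)`.
#' @param n_modulator Number of nonzero modulator concentrations
#'   (>= 4), geometric with ratio `10^0.5` starting at `10^-(pKb + 3)`;
#'   vehicle 0 is always added.
#' @return A [concentration_grid()].
#' @export
make_interaction_design <- function(truth, n_agonist = 13L,
                                    n_modulator = 9L) {
  if (n_agonist < 6) stop("n_agonist must be >= 6")
  if (n_modulator < 4) stop("n_modulator must be >= 4")
  if (inherits(truth, "binding_params")) {
    pk_ag <- truth$pKi_agonist
    pk_mod <- truth$pKb_modulator
    lstar <- 10^(-truth$pKd_radioligand)
  } else if (inherits(truth, "functional_params")) {
    pk_ag <- truth$pKa_agonist
    pk_mod <- truth$pKb_modulator
    lstar <- NA_real_
  } else stop("truth must be binding_params or functional_params")
  ag <- 10^(-(pk_ag + 3)) * 10^(0.5 * (seq_len(n_agonist) - 1))
  mod <- c(0, 10^(-(pk_mod + 3)) * 10^(0.5 * (seq_len(n_modulator) - 1)))
  concentration_grid(agonist_concs = c(0, ag), modulator_concs = mod,
                     radioligand_conc = lstar)
}

#' Simulate interaction-binding experiments
#'
#' Evaluates the allosteric ternary complex model (fractional specific
#' binding) on the design grid and adds seeded noise; with `sd = 0` the
#' values equal the model predictions exactly.
#'
#' @param truth A [binding_params()] object.
#' @param design A [concentration_grid()] with a radioligand
#'   concentration.
#' @param noise A [noise_model()]; default additive Gaussian, sd 0.03
#'   of the specific-binding fraction.
#' @param n_experiments Number of replicate experiments (default 3).
#' @param seed RNG seed; replicates differ only through seeded noise.
#' @param agonist,modulator Labels attached to the datasets.
#' @return List of [assay_dataset()] objects, one per replicate.
#' @export
simulate_interaction_binding <- function(truth, design,
                                         noise = noise_model(),
                                         n_experiments = 3L, seed = 0L,
                                         agonist = NA_character_,
                                         modulator = NA_character_) {
  stopifnot(inherits(truth, "binding_params"),
            inherits(design, "concentration_grid"))
  g <- design$grid
  mu <- atcm_fractional_occupancy(g$radioligand_conc_M,
                                  g$agonist_conc_M,
                                  g$modulator_conc_M, truth)
  set.seed(seed)
  lapply(seq_len(n_experiments), function(r) {
    d <- g
    d$value <- apply_noise(mu, noise)
    assay_dataset(d, "interaction_binding", agonist = agonist,
                  modulator = modulator, replicate = r,
                  normalization = "fractional specific binding")
  })
}

#' Simulate functional interaction experiments
#'
#' As [simulate_interaction_binding()], for concentration-response data
#' generated from the operational model of allosterism and agonism.
#'
#' @param truth A [functional_params()] object.
#' @param design A [concentration_grid()].
#' @param noise A [noise_model()]; default additive Gaussian, sd 3
#'   response units on Em = 100.
#' @param n_experiments,seed,agonist,modulator As in
#'   [simulate_interaction_binding()].
#' @return List of [assay_dataset()] objects.
#' @export
simulate_functional_interaction <- function(truth, design,
                                            noise = noise_model(sd = 3),
                                            n_experiments = 3L,
                                            seed = 0L,
                                            agonist = NA_character_,
                                            modulator = NA_character_) {
  stopifnot(inherits(truth, "functional_params"),
            inherits(design, "concentration_grid"))
  g <- design$grid
  mu <- operational_allosterism_response(g$agonist_conc_M,
                                         g$modulator_conc_M, truth)
  set.seed(seed)
  lapply(seq_len(n_experiments), function(r) {
    d <- g
    d$value <- apply_noise(mu, noise)
    assay_dataset(d, "functional", agonist = agonist,
                  modulator = modulator, replicate = r,
                  normalization = "percent of maximal agonist response")
  })
}

#' Simulate a full interaction study from a published preset
#'
#' Convenience wrappers that expand a [truth_presets()] entry into the
#' per-agonist truths, build the standard designs and simulate every
#' agonist's datasets with consistent replicate indexing, ready for the
#' global fitters.
#'
#' @param preset A preset name (see [truth_presets()]) or a preset
#'   entry.
#' @param noise,n_experiments,seed As in the underlying simulators.
#' @param n_agonist,n_modulator Design sizes.
#' @return List of [assay_dataset()] objects over all agonists and
#'   replicates.
#' @export
simulate_binding_preset <- function(preset, noise = noise_model(),
                                    n_experiments = 3L, seed = 0L,
                                    n_agonist = 13L, n_modulator = 9L) {
  p <- resolve_preset(preset, "binding")
  out <- list()
  i <- 0L
  for (ag in names(p$agonists)) {
    truth <- binding_params(pKd_radioligand = p$pKd_radioligand,
                            pKi_agonist = p$agonists[[ag]]$pKi,
                            pKb_modulator = p$pKb,
                            log_alpha = p$agonists[[ag]]$log_alpha,
                            log_alpha_prime = p$log_alpha_prime)
    design <- make_interaction_design(truth, n_agonist, n_modulator)
    out <- c(out, simulate_interaction_binding(
      truth, design, noise, n_experiments, seed = seed + i,
      agonist = ag, modulator = p$modulator))
    i <- i + 1L
  }
  out
}

#' @rdname simulate_binding_preset
#' @export
simulate_functional_preset <- function(preset, noise = noise_model(sd = 3),
                                       n_experiments = 3L, seed = 0L,
                                       n_agonist = 13L,
                                       n_modulator = 9L) {
  p <- resolve_preset(preset, "functional")
  out <- list()
  i <- 0L
  for (ag in names(p$agonists)) {
    a <- p$agonists[[ag]]
    truth <- functional_params(pKa_agonist = a$pKa,
                               pKb_modulator = p$pKb,
                               log_tau_A = a$log_tau_A,
                               log_tau_B = p$log_tau_B,
                               log_alphabeta = a$log_alphabeta,
                               log_alpha = a$log_alpha)
    design <- make_interaction_design(truth, n_agonist, n_modulator)
    out <- c(out, simulate_functional_interaction(
      truth, design, noise, n_experiments, seed = seed + i,
      agonist = ag, modulator = p$modulator))
    i <- i + 1L
  }
  out
}

resolve_preset <- function(preset, kind) {
  if (is.character(preset)) {
    all <- truth_presets()
    if (!preset %in% names(all)) stop("unknown preset: ", preset)
    p <- all[[preset]]
    p$modulator <- sub(".*_", "", preset)
  } else p <- preset
  if (!identical(p$kind, kind))
    stop("preset is of kind '", p$kind, "', expected '", kind, "'")
  if (is.null(p$modulator)) p$modulator <- NA_character_
  p
}

#' Reference trajectories with known geometry
#'
#' Deterministic coordinate constructions whose RMSD, RMSF and dihedral
#' values are known in closed form, used as oracles for the geometry
#' metrics.
#'
#' * `static`: a rigid 6-atom arrangement repeated unchanged.
#' * `rigid_motion`: the same arrangement under a per-frame rotation
#'   plus translation (fitted RMSD 0, unfitted > 0).
#' * `single_atom_oscillation`: atoms 1-5 fixed, atom 6 displaced
#'   `+/- amplitude` along x in alternating frames (RMSF of atom 6 =
#'   amplitude when fitting on atoms 1-5).
#' * `torsion_sweep`: a 4-atom chain whose dihedral sweeps 0 to 180
#'   degrees evenly over the frames.
#'
#' @param kind Trajectory kind.
#' @param n_frames Number of frames (>= 1).
#' @param seed Seed for the rigid-motion rotations.
#' @param amplitude Oscillation amplitude (Angstrom).
#' @return An `md_trajectory`.
#' @export
make_reference_trajectory <- function(kind = c("static", "rigid_motion",
                                               "single_atom_oscillation",
                                               "torsion_sweep"),
                                      n_frames = 20L, seed = 0L,
                                      amplitude = 1) {
  kind <- match.arg(kind)
  if (n_frames < 1) stop("n_frames must be >= 1")
  base <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.3, 0),
                c(0.75, 0.4, 1.2), c(-0.5, 0.8, 0.5), c(2.0, 1.0, 0.8))
  rot <- function(theta, axis) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  }
  coords <- switch(kind,
    static = {
      a <- array(NA_real_, c(n_frames, 6, 3))
      for (f in seq_len(n_frames)) a[f, , ] <- base
      a
    },
    rigid_motion = {
      set.seed(seed)
      axis <- stats::rnorm(3)
      a <- array(NA_real_, c(n_frames, 6, 3))
      for (f in seq_len(n_frames)) {
        R <- rot(2 * pi * (f - 1) / n_frames, axis)
        shift <- c(f * 0.7, -f * 0.3, f * 0.1)
        a[f, , ] <- sweep(base %*% t(R), 2, shift, `+`)
      }
      a
    },
    single_atom_oscillation = {
      a <- array(NA_real_, c(n_frames, 6, 3))
      for (f in seq_len(n_frames)) {
        m <- base
        m[6, 1] <- m[6, 1] + if (f %% 2 == 0) amplitude else -amplitude
        a[f, , ] <- m
      }
      a
    },
    torsion_sweep = {
      a <- array(NA_real_, c(n_frames, 4, 3))
      angles <- if (n_frames == 1) 0 else
        pi * (seq_len(n_frames) - 1) / (n_frames - 1)
      for (f in seq_len(n_frames)) {
        th <- angles[f]
        a[f, , ] <- rbind(c(1, 0, -1), c(0, 0, 0), c(0, 0, 1.5),
                          c(cos(th), sin(th), 2.5))
      }
      a
    })
  trajectory(coords)
}
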