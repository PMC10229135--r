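---
title: "Quantifying GPCR allosteric modulation and reweighting accelerated dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GPCR allosteric modulation and reweighting accelerated dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomod)
```

# The pharmacological models

## Allosteric ternary complex model (ATCM)

Interaction binding assays measure specific binding of a radiolabelled
orthosteric probe (here an NMS-like antagonist, held at a fixed
concentration near its equilibrium dissociation constant $K_{A^*}$)
across a grid of agonist ($I$) and allosteric modulator ($B$)
concentrations.  At equilibrium the fraction of receptors occupied by
the probe is

$$\rho = \frac{[L^*]}{[L^*] + K_{A^*}
  \dfrac{1 + \tfrac{[I]}{K_I} + \tfrac{[B]}{K_B}
         + \alpha\tfrac{[I][B]}{K_I K_B}}
        {1 + \alpha'\tfrac{[B]}{K_B}}}$$

where $\alpha$ is the binding cooperativity between agonist and
modulator and $\alpha'$ the cooperativity between the probe and the
modulator.  $\alpha > 1$ is positive modulation; $\alpha = 1$ renders
the modulator invisible to the probe ($\alpha' = 1$), which
`atcm_fractional_occupancy()` reproduces exactly (the Cheng–Prusoff
reduction is a unit-tested property).  All affinities and
cooperativities are carried in log10 space ($pK_I$, $pK_B$,
$\log\alpha$), which keeps the optimization well scaled and matches how
such parameters are conventionally reported.  Concentration zero is
always treated exactly — model functions never log-transform
concentrations.

A consequence used as an acceptance property: with a saturating
modulator ($B \gg K_B$, $\alpha' = 1$) the agonist potency shifts by
exactly the fold cooperativity, $IC_{50}(0)/IC_{50}(B\to\infty) \to
\alpha$.  The package measures this shift numerically by root-finding
on the occupancy curve.

## Operational models of agonism and allosterism

Functional responses follow the Black–Leff operational model: agonist
occupancy is transduced with efficacy $\tau_A$ (which lumps receptor
density and coupling efficiency) through

$$E = \mathrm{basal} + (E_m - \mathrm{basal})
  \frac{\tau_A^n A^n}{(A + K_A)^n + \tau_A^n A^n}.$$

For agonist–modulator interactions the package uses the standard
operational-allosterism form (the one implemented by common
curve-fitting templates):

$$E = \mathrm{basal} + (E_m - \mathrm{basal})\frac{N^n}{D^n + N^n},
\qquad
\begin{aligned}
N &= \tau_A A (K_B + \alpha\beta B) + \tau_B B K_A\\
D &= A K_B + K_A K_B + K_A B + \alpha A B
\end{aligned}$$

with $\alpha\beta$ the functional cooperativity and $\tau_B$ the
modulator's own operational efficacy (direct allosteric agonism).  The
form reduces algebraically to the agonism model at $B = 0$, which is
asserted as a test invariant rather than assumed.  The
efficacy-modulation component is recovered as
$\log\beta = \log\alpha\beta - \log\alpha$, with uncertainty propagated
as the root of summed squared SEMs (`propagate_sem()`).

Defaults reflect how such data are normalized in practice: $E_m$ fixed
at 100 (responses scaled to the maximal agonist response), basal 0,
transducer slope $n = 1$ (freed only via an explicit
`parameter_spec`).  Whether $E_m$ is shared between curves within one
assay is not something the data usually decide; the package defaults
to a fixed shared $E_m$ and exposes `fit_em` for the alternative.

## Global fitting strategy

`fit_atcm_global()` and `fit_operational_allosterism_global()` follow
the reporting conventions of interaction studies:

* the modulator affinity $pK_B$ is one shared parameter across all
  agonist datasets; per agonist the fit estimates $pK_I$ (or
  $\log\tau_A$) and $\log\alpha$ (or $\log\alpha\beta$);
* the probe affinity $pK_{A^*}$ is fixed from saturation binding, and
  functional fits fix all binding affinities from the binding assays;
* $\log\alpha'$ (probe–modulator cooperativity) is fixed at 0 by
  default — appropriate for a probe the modulator is neutral toward —
  and freed through a `parameter_spec` when the modulator is known to
  affect probe binding;
* each replicate experiment is fit separately and replicates are
  summarized as mean ± SEM (`method = "replicates"`, the default), with
  a pooled single regression (asymptotic SEs from a finite-difference
  Jacobian) available for comparison.

The optimizer is bounded Levenberg–Marquardt (minpack.lm) with
multi-start: the data-driven initial guess (IC50/EC50 read off the
modulator-free curve, Cheng–Prusoff corrected) plus `n_starts - 1`
starts jittered uniformly within ±1 log unit, seeded by the `seed`
argument.  Ties are broken by lowest residual sum of squares, then
lowest parameter norm.  Noiseless data generated anywhere inside the
bounds are recovered to better than $10^{-4}$ log units from any of the
tested start sets; this round-trip over every stored preset is part of
the acceptance suite.

# Synthetic data: what it emulates, and what it does not

No raw assay data accompany the published parameter tables, so the
package reproduces them as parameter-recovery experiments: the
transcribed parameter sets (`truth_presets()`, cross-checked against
`inst/extdata/published_parameters.csv` by a double-entry test) are the
generating truths, and the fitted values are compared back to the
printed numbers.

The generator mirrors the published assay designs: radioligand at its
$K_D$, agonist half-log dilutions spanning $pK \pm 3$, modulator
half-log series from $pK_B + 3$ to $pK_B - 1$ plus vehicle, three
independent replicate experiments.  The noise model is additive
Gaussian — SD 0.03 of the specific-binding fraction for binding, 3
response units on $E_m = 100$ for functional data — chosen once so that
the recovered SEMs are of the same order as the published ones.  Real
assay noise is certainly not exactly this (counts are heteroscedastic,
plates have edge effects, nonspecific binding is estimated rather than
known), so passing recovery tests demonstrate correctness of the
estimation machinery under the declared noise model, not robustness to
real-world artifacts.  Radioligand depletion and pre-equilibrium
kinetics are deliberately out of scope.

Two table-transcription notes.  First, where a published functional
table leaves the agonist-efficacy cells blank for the second modulator
(they were shared within one assay), the presets carry the shared
values explicitly, with the provenance note saying so.  Second, the
mutant-panel preset with a non-neutral probe cooperativity
($\log\alpha_{NMS} = -1.10$) is fit with $\log\alpha'$ freed, which
exercises that code path end to end.

# The accelerated-dynamics engine

## Boost potential

Gaussian-accelerated dynamics adds a harmonic boost below a threshold
energy $E$:

$$\Delta V(r) = \tfrac{1}{2}k\,(E - V(r))^2 \quad\text{for } V(r) < E,
\qquad 0 \text{ otherwise.}$$

$E$ and $k$ are set from sampled potential statistics
($V_{min}, V_{max}, V_{avg}, \sigma_V$) under three principles: the
boosted surface preserves the order of potential values, reduces their
gaps, and keeps the boost SD below a user limit $\sigma_0$ (default
6.0 kcal/mol) so that cumulant reweighting stays accurate.  These force
$V_{max} \le E \le V_{min} + 1/k$.  With the threshold at its lower
bound, $E = V_{max}$ and

$$k_0 = \min\!\left(1,\;
  \frac{\sigma_0}{\sigma_V}\frac{V_{max}-V_{min}}{V_{max}-V_{avg}}
  \right), \qquad k = \frac{k_0}{V_{max}-V_{min}}.$$

With the threshold at its upper bound $E = V_{min} + 1/k$,
$k_0'' = (1 - \sigma_0/\sigma_V)(V_{max}-V_{min})/(V_{avg}-V_{min})$,
accepted iff $0 < k_0'' \le 1$ and otherwise falling back to the
lower-bound formula.  The acceptance condition is stated ambiguously in
parts of the literature; the fallback rule here is the one consistent
with the original method.  Degenerate statistics are handled
explicitly: $V_{max} = V_{min}$ disables the boost (flagged),
$\sigma_V = 0$ saturates $k_0$ at 1 in lower mode.

## Integrator and units

The engine targets analytic toy surfaces, not solvated biomolecules:
Langevin dynamics with BAOAB splitting, unit particle mass, energies in
kcal/mol, $k_B = 0.0019872041$ kcal/mol/K, default temperature 300 K,
and a reduced time unit with default $dt = 10^{-3}$ (the tests and
acceptance runs use $dt = 0.01$, small against the well frequency
$\omega \approx 7.5$ of the reference double well).  On the boosted
surface forces are the plain forces scaled by $1 - k(E - V) \in [0,1]$.
A three-stage protocol mirrors production practice: conventional
dynamics to collect potential statistics, boosted equilibration with
the boost re-estimated every `update_interval` steps from the
accumulated statistics, then production with frozen parameters.
Whether production parameters were frozen or continually updated in
published protocols is ambiguous; freezing makes every production
frame's weight exact under one bias, so that is the default here.  The
boosted-equilibration stage matters: the initial statistics stage only
sees one basin, and it is the updates during boosted sampling that let
$V_{max}$ (hence the boost strength) converge; the acceptance runs use
$2\times10^5$ equilibration steps with updates every $2\times10^4$.

The three stages seed the RNG with `seed`, `seed + 1` and `seed + 2`
respectively, so a production segment can be reproduced in isolation —
the zero-boost equivalence test exploits this to show bit-identity with
conventional dynamics.  Dual-boost (an independent boost on the first
additive term of a decomposed surface plus one on the total potential,
boosts summed per frame) is available for surfaces exposing a
`terms` decomposition and mimics the dihedral-plus-total arrangement of
production dual-boost simulations; the default is total-boost only.

## Energetic reweighting

The canonical profile along a coordinate binned into $M$ bins is
recovered by weighting each bin's population with the
ensemble-averaged Boltzmann factor of the boost,
$\langle e^{\beta\Delta V}\rangle_j$ with $\beta = 1/k_BT$, estimated
either directly (`exponential`) or by second-order cumulant expansion
(`cumulant2`, the default):

$$\langle e^{\beta\Delta V}\rangle \approx
  \exp\!\left(\beta C_1 + \tfrac{\beta^2}{2} C_2\right),
  \qquad C_1 = \langle\Delta V\rangle,\;
  C_2 = \sigma^2_{\Delta V}.$$

For exactly Gaussian per-bin boost the two coincide with the
closed-form lognormal mean $\exp(\beta\mu + \beta^2\sigma^2/2)$ — a
test constructs standardized antithetic Gaussian samples so the
identity can be asserted to $10^{-3}$ without sampling slack.  The
exponential estimator is noisy and can overflow for broad boosts;
non-finite weights are flagged with a pointer to `cumulant2`.
`boost_gaussianity()` reports per-bin skewness and excess kurtosis
(flagging $|skew| > 0.5$) as the usual reliability diagnostic.

Bins with fewer than `cutoff_frames` frames (default 500) are dropped
before normalization; the reweighted probabilities over retained bins
sum to 1 and the PMF is shifted to minimum 0.  A constant boost
cancels in the normalization, and zero boost reduces to the plain
histogram PMF — both unit-tested identities.

## Problem sizes and convergence

The reference experiment is the 1D double well $a(x^2-b^2)^2$ with
$a = 7$, $b = 1$ (barrier $ab^4 = 7$ kcal/mol $\approx 11.7\,k_BT$ at
300 K), $\sigma_0 = 6$ kcal/mol, friction 1.  The boost lifts the wells
by roughly half the barrier, which raises well-to-well crossings from
essentially none in conventional runs to tens per $10^6$ steps.  The
dominant PMF error is then the well-population imbalance, which shrinks
with the number of crossings; the acceptance script therefore combines
three independent $10^6$-step productions (independent seeds), as is
standard for such simulations, before reweighting with 0.1-unit bins
and the 500-frame cutoff.  The per-bin error against the analytic
bin-integrated Boltzmann profile is required to stay below
0.5 kcal/mol.  Barrier-top bins typically fall under the frame cutoff
and are excluded by construction rather than silently extrapolated.

# Trajectory geometry

`superpose_kabsch()` implements the SVD solution with the reflection
branch corrected by a sign flip (proper rotation, $\det = +1$);
collinear selections are rejected since the in-line rotation is
undetermined.  `rmsd_series()` separates the fit selection from the
measure selection, supporting ligand-RMSD-after-receptor-fit.
`rmsf()` aligns to an iteratively refined mean structure (two passes);
the alignment reference is a genuine choice the metric's definition
leaves open, and the mean structure is the common one.  Dihedrals use
the signed atan2 convention (cis 0°, trans 180°, range
$(-180°, 180°]$); for a tryptophan $\chi_2$ the conventional quadruple
is CA–CB–CG–CD1.  Ring-to-group "distances" are computed between
centroids by default — the closest-atom alternative is not implemented
because no published definition was being matched.  The bio3d package
serves as an independent cross-check for superposition RMSD and
torsions in the test suite; the implementations here are self-contained.

# Known limitations

* Recovery guarantees hold under the declared synthetic noise model
  only; no claim is made about robustness to real plate artifacts.
* The engine is 1D/2D with reduced units; nothing about force fields,
  boundary conditions, constraints or barostats transfers.
* The exponential reweighting estimator is reported but not
  recommended for boosts broader than a few $k_BT$.
* Bayesian uncertainty, model selection between cooperativity models,
  and Schild analysis are out of scope.

# Command-line use

`inst/scripts/allomod.R` exposes the same functionality as
subcommands (`simulate-binding`, `fit-binding`, `simulate-functional`,
`fit-functional`, `report`, `gamd-demo`, `reweight`, `traj-analyze`);
each stage logs the package version, seed and a config hash so any run
is reproducible from its log line.  `allomod_cli()` is the same entry
point callable from R.
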