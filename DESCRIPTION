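Package: allomod
Title: Quantitative Pharmacology of GPCR Allosteric Modulation and
    Gaussian Accelerated Dynamics Reweighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying allosteric modulation at G
    protein-coupled receptors and for desk-scale enhanced-sampling
    simulation experiments.  Implements the allosteric ternary complex
    model for radioligand interaction binding, the Black-Leff
    operational models of agonism and allosterism, and global nonlinear
    least-squares fitting with parameter sharing, fixing, replicate
    summaries, derived cooperativity parameters and error propagation.
    Also provides a Gaussian accelerated dynamics engine on analytic toy
    potentials (harmonic boost parameterization, Langevin BAOAB
    integration, cumulant-expansion energetic reweighting to potentials
    of mean force), trajectory geometry metrics (Kabsch superposition
    RMSD, RMSF, distances, dihedral angles), and synthetic assay-data
    generators with published parameter sets as generating truths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
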