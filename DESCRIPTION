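Package: cspfit
Title: NMR Chemical Shift Perturbation Titration Analysis with
    Ligand-Depletion Kd Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of protein-ligand titrations followed by 1H-15N HSQC
    NMR under fast exchange. Computes normalized chemical shift
    perturbations (CSPs) from assigned Sparky-style peak lists, classifies
    significantly perturbed resonances by a trimmed mean-plus-SD threshold,
    fits per-residue dissociation constants with the single-site binding
    isotherm accounting for ligand depletion, and aggregates them into a
    global Kd with outlier-removal and lower-limit reporting rules. Includes
    a seeded synthetic titration generator with known ground truth for
    validation, and a stranded maxgap peak-overlap module for genomic BED
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
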