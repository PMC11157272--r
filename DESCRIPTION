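Package: titravol
Title: Equilibrium Binding Analysis, AFM Volumetry and Stoichiometry of
    Protein-DNA Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying transcription-factor/enzyme
    interactions on DNA, built around biolayer-interferometry (BLI)
    equilibrium titrations. Fits plateau titration curves with either the
    hyperbolic binding isotherm or the ligand-depletion (Morrison) quadratic
    model, classifies the binding regime from the ratio of the fixed-component
    concentration to the dissociation constant, and performs global
    multi-curve fits sharing a single Kd with per-curve baseline, amplitude
    and effective immobilized-DNA concentration. Companion tools convert
    atomic force microscopy (AFM) peak measurements to particle volumes and
    molecular weights via a protein specific volume, subtract adjacent-DNA
    volume, cluster one-dimensional mass distributions into stoichiometry
    classes by exact dynamic programming, and assign classes to dimer-multiple
    reference ladders. Additional helpers cover luciferase-assay fold-change
    normalisation with error propagation, ATP calibration, growth-curve
    half-maximal timing and strain growth delays, voxel-based
    solvent-excluded-volume estimation from structures, and seeded synthetic
    data generators for every input kind.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
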