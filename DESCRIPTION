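Package: rltsim
Title: Microenvironment-Scale Simulation of PSMA-Directed Radioligand Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Histology-driven in silico platform for PSMA-directed radioligand
    therapy at the tumor-microenvironment scale. Builds computational domains
    from binarized vessel maps (anti-CD31 histology or synthetic maps with
    prescribed vascular fraction and clustering), solves the steady-state
    oxygen reaction-diffusion equation with Michaelis-Menten consumption and
    segments tissue into McKeown oxygenation classes, propagates radiolabeled
    PSMA-ligands with a three-compartment convection-reaction-diffusion model
    driven by a parametric arterial input function, converts time-integrated
    activity to absorbed dose with MIRD-style voxel S-value kernels for
    177Lu and 225Ac, summarizes dose with dose-to-tissue histograms, and maps
    dose and oxygenation to cell survival with oxygen-dependent
    linear-quadratic radiobiology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
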