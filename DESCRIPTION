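Package: stripcount
Title: Counting Enzymes Immobilized on Nanoparticle-Coated Electrodes by
    Anodic Stripping Coulometry and Fluorimetry
Version: 0.1.0
Authors@R:
    person("Analytical", "Methods Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts integrated voltammetric charges from gold-oxide
    reduction and anodic stripping of electrodeposited gold nanoparticles
    into the ensemble mean particle radius, particle count, total gold
    surface area and electrode coverage, and converts fluorescence of
    enzymes released by the stripping step into absolute enzyme counts,
    enzymes per nanoparticle and per-enzyme footprint.  Includes
    voltammogram file I/O with cycle segmentation, baseline-corrected peak
    integration, linear fluorescence calibration with inverse prediction,
    SEM particle-table sizing, a forward simulator of all raw inputs for
    parameter-recovery testing, and a command-line pipeline with cohort
    aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
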