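Package: bundleIMS
Title: Native Ion Mobility-Mass Spectrometry Analysis of DNA Helix-Bundle Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the self-assembly of DNA helix-bundle
    nanostructures by native ion mobility-mass spectrometry (IM-MS).
    Covers oligonucleotide mass chemistry (average masses, terminal groups,
    salt adducts, m/z for either polarity), enumeration of contiguous
    oligomer compositions on a cyclic strand-connectivity map, synthetic
    IM-MS data generation with ground truth, charge-series detection and
    neutral-mass deconvolution, stoichiometry assignment, mobility-separated
    abundance quantification, travelling-wave collision cross section (CCS)
    calibration, coarse-grained bead-model builders for helix-bundle
    geometries (including laterally squished gas-phase variants), Monte
    Carlo projection-approximation and exact hard-sphere scattering CCS
    estimators, and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
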