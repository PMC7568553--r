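Package: diaharmony
Title: Multi-Site HRMS1-DIA Harmonization: Simulation, QC Gating, and
    Ratio-Based Protein Roll-Up
Version: 0.1.0
Authors@R:
    person("DIA", "Harmony Maintainers", email = "maintainers@diaharmony.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking label-free quantification in
    multi-laboratory data-independent acquisition (DIA) proteomics studies.
    Models the HRMS1-DIA acquisition geometry (isolation-window tiling,
    MS1/MS2 cycle timing and chromatographic sampling density), reads and
    writes Spectronaut-dialect precursor reports and run manifests,
    generates synthetic multi-site three-organism mixture studies with
    known ground-truth ratios, computes the six LC-MS system-suitability
    metrics with pass/fail triage of chromatographic versus
    mass-spectrometric failures, performs peptide-to-protein roll-up by
    the geometric median of inter-sample pairwise ratios (controlled
    mixtures) or summed intensities (tissue cohorts), and scores
    quantitative performance against theoretical abundance ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
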