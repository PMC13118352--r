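Package: fluorbind
Title: Protein-Ligand Binding Analysis from Fluorescence Quenching Titrations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of protein-ligand interactions from steady-state
    spectroscopic measurements: inner-filter-effect correction of
    fluorescence titrations, free/bound ligand partitioning, Klotz
    double-reciprocal and Stern-Volmer quenching fits, van't Hoff binding
    thermodynamics, two-state thermal-melt (Tm) estimation from F330/F350
    ratio curves, oxidative-protection metrics from fluorescence decay
    traces, catalase activity from A240 kinetics, and fourth-derivative
    UV spectroscopy. Includes seeded forward-model generators for every
    data family so that each estimator can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
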