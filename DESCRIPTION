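Package: wishplan
Title: Prioritized Multi-Criteria Radiotherapy Plan Optimization on Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for automated prioritized ("wish-list")
    multi-criteria fluence-map optimization of postoperative gastric
    radiotherapy plans, with downstream plan evaluation. Generates seeded
    synthetic abdominal voxel phantoms and pencil-beam influence matrices,
    solves the lexicographic epsilon-constraint planning problem defined by a
    prioritized wish-list (LTCP, generalized EUD, mean-dose, maximum-dose and
    dose-volume objectives under hard maximum-dose constraints), and evaluates
    plans via cumulative dose-volume histograms, homogeneity and conformity
    indices, integral-dose summaries, linear-quadratic fractionation
    correction, Lyman-Kutcher-Burman normal tissue complication probabilities,
    and paired Wilcoxon signed-rank comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
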