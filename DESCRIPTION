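Package: alfe
Title: Active-Learning-Guided Alchemical Free Energy Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hit-optimization campaigns that couple alchemical
    relative binding free energy (RBFE) calculations with active learning.
    Provides substructure and similarity filtering of analog libraries,
    docking-pose filter cascades, thermodynamic integration with on-the-fly
    convergence control (automatic equilibration detection, decorrelation,
    Jensen-Shannon convergence testing and simulation-extension policy),
    perturbation-map bookkeeping with RBFE-to-ABFE conversion, an AutoML
    active-learning acquisition loop over molecular fingerprints, and fully
    synthetic generators (analog libraries, affinity oracles, mock docking
    tables, gradient time series with known free energies) so the whole
    workflow can be exercised and validated without molecular dynamics or
    docking engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    pracma,
    randomForest,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
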