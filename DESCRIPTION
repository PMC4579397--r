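Package: PhosphoLogic
Title: Boolean Logic Models of Signal Propagation from Perturbation
    Phosphoproteomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trains Boolean logic models of kinase signalling from discovery
    phosphoproteomics perturbation screens. Phosphopeptide intensities are
    normalized and summarised as per-condition effects with moderated
    statistics, Booleanized per peptide with Gaussian mixture models into
    control/perturbed evidence scores, and mapped onto a background network of
    kinase/phosphatase-substrate interactions connecting drug targets to
    perturbed phosphosites. Candidate logic models are then sampled, simulated
    to their monotone fixpoint, scored against the evidence, and the sampling
    weights evolved under a capped correction rule; consensus networks are
    extracted from edge frequencies combined across independent runs. A
    synthetic-data generator with planted ground-truth models supports
    end-to-end benchmarking and parameter-recovery studies.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    mclust,
    igraph,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
biocViews: Network, NetworkInference, Proteomics, SystemsBiology, Software
RoxygenNote: 7.3.3
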