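Package: glyconet
Title: Gaussian Graphical Model Inference of the IgG Glycosylation Pathway
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers enzymatic reactions in the human IgG Fc N-glycosylation
    pathway from large-scale glycomics abundance data. Builds Pearson and
    shrinkage-based partial correlation (Gaussian graphical model) networks
    across IgG subclasses, quantifies their overlap with candidate pathway
    models through pathway distances and Fisher's exact tests, extends the
    known glycosylation pathway with rule-based sets of candidate reactions
    selected by bootstrap model comparison, and supports subclass modularity
    analysis with degree-preserving rewiring nulls, cross-cohort replication,
    and product-substrate ratio traits with p-gain statistics. Includes a
    synthetic-cohort generator whose conditional-independence structure
    matches a chosen pathway model, for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
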