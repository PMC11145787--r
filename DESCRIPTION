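Package: hmcReg
Title: Gene Regulation from 5-Hydroxymethylcytosine Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts per-gene expression state (High/Low) from binned
    5-hydroxymethylcytosine (5hmC) enrichment with a fully connected
    neural classifier, decodes per-bin feature importance with a
    DeepLift (Rescale) attribution, and prioritizes putative enhancers
    by an Activity-by-Contact score using 5hmC as the activity signal
    and by a GraphSAGE classifier on Hi-C contact graphs decoded with
    an edge-mask explainer. Includes Hi-C contact-map utilities (ICE
    balancing, diagonal-median distance normalization, top-k neighbor
    graphs, down-sampling and aggregation) and seeded synthetic-genome
    generators so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    e1071,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
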