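Package: efcascade
Title: Epigenetic-Factor Regulation by the Cortical Pax6-Tbr2-Tbr1 Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping how sequentially expressed cortical transcription
    factors (Pax6, Tbr2, Tbr1) regulate the epigenetic-factor landscape of the
    developing neocortex. The package classifies genes by cortical cell type
    (radial glia, intermediate progenitors, neurons) from lineage-sorted
    expression and zonal in situ profiles, calls rostrocaudal expression
    gradients, annotates transcription-factor ChIP-seq peaks to genes with a
    50 kb binding window, computes knockout differential expression, intersects
    binding with expression changes to call direct activation, repression, and
    Tbr1/Tbr2 synergy, and assembles the signed regulatory network with
    feedforward/feedback motif detection and summary reporting. A synthetic-data
    module generates all pipeline inputs with planted ground truth so every
    stage can be exercised and benchmarked offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
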