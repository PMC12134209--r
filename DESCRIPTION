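Package: chromofied
Title: Quantification of Histone-Variant Enrichment at Mouse Chromocenters
Version: 0.1.0
Authors@R:
    person("Chromofied", "Maintainers", email = "maintainers@chromofied.dev",
           role = c("aut", "cre"))
Description: Tools to quantify histone H3 variant (H3.1/H3.2 versus H3.3)
    enrichment at DAPI-dense chromocenters (pericentric heterochromatin) in
    mouse nuclei. Implements 3D fluorescence-intensity enrichment at domains
    (in/out intensity ratios per nucleus and per chromocenter), rule-based
    classification of nuclear patterns (Enriched / Even / Excluded),
    cell-cycle staging from EdU and Aurora-B markers including S-phase
    sub-staging from the spatial EdU pattern, FUCCI (hCdt1/Geminin) intensity
    gating, and repeat-element ChIP (SNAP-capture-seq) enrichment
    normalization (CPM, length, input, log2, z-score) with repeat-class
    summaries. A synthetic-data module generates ground-truthed 3D nuclear
    image stacks and repeat-level fragment counts so that every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    withr,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
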