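Package: promethylome
Title: Promoter DNA Methylation Profiling from MeDIP Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for promoter DNA methylation profiles
    measured by methylated-DNA immunoprecipitation (MeDIP) on promoter
    tiling arrays, compared across embryonic stem cells, ES-derived germ
    layers and adult tissues. Provides a synthetic-data generator with
    planted ground truth (probe layout, CpG-density-aware enrichment,
    commonly methylated germline promoters, imprinting centers,
    tissue-specific differentially methylated regions, histone states and
    expression), robust windowed probe scoring with empirical false
    discovery rate calibration from an input-swap null, CpG-density-gated
    candidate methylated region calling with tri-state methylation calls,
    cross-sample commonality categorisation and TSS-distance methylation
    profiles, testis-specificity gene-set enrichment with a
    gene-permutation null, and integration of promoter histone states
    (H3K4me3/H3K27me3/bivalent/none) with methylation and expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    fgsea,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
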