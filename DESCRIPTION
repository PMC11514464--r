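Package: chromassoc
Title: Chromatin Association Analytics for Broad ChIP-Seq Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream association analytics for broad chromatin
    immunoprecipitation (ChIP-seq) domains such as lamina-associated
    domains and EDD-style enrichment peaks: base-pair overlap partitions
    (Venn classes) of interval sets, a region-randomization overlap
    permutation test with Z-score and empirical p-value, closest-distance
    distributions with Kolmogorov-Smirnov comparisons and Hochberg
    correction, windowed per-gene binding scores with top-decile "bound"
    classification, scaled meta-region and anchor-centred signal profiles,
    threshold rules for expressed/differentially-expressed gene classes,
    ChIP-qPCR batch normalization, and a seeded synthetic-data generator
    that emulates the statistical structure of such studies so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
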