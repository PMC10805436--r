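Package: coevscan
Title: Selection Scans and Co-Evolution Analysis for Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed Tajima's D and Weir-Cockerham FST with empirical null
    distributions, EHH/iHS and beta-score selection scans, a distance-binned
    matched-window null for detecting unusual linkage disequilibrium within
    gene clusters, per-SNP eQTL linear models, and Mendelian randomization
    (IVW, MR-Egger, weighted median) with LD-correlated instruments. Ships a
    synthetic-data module (Balding-Nichols genotypes, coalescent windows,
    constructed sweeps, two-locus LD pairs, expression and MR summary
    statistics with known truth) so every stage is testable end to end
    without external cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    tools,
    vcfR,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
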