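Package: popgenscan
Title: Sliding-Window Population-Genomic Scans, Sweep Detection and
    Assembly-Junction Validation for Structured Plant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resequencing-based population genomics of small
    structured cohorts: Hardy-Weinberg exact-test SNP filtering, per-population
    diversity indices (observed/expected heterozygosity, Nei's unbiased gene
    diversity, Shannon-Wiener index, allele number), sliding-window nucleotide
    diversity (pi) and Weir-Cockerham Fst, joint top-quantile Fst x pi-ratio
    selective-sweep scans, and linkage-disequilibrium-based validation of
    assembly contig junctions. Includes seeded hierarchical Balding-Nichols and
    recombining-haplotype simulators emulating a multi-region sampling design,
    plus assembly-report arithmetic (Nxx, anchoring ratio, BUSCO and
    composition percentages).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    BiocGenerics,
    optparse,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
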