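Package: strainvar
Title: Variant-Site Filtering and Divergence Analysis for Inbred Strain Resequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for short-read resequencing of near-fully homozygous
    (inbred) strain panels. Implements averaged quality-value read trimming
    and paired-read selection, identity-based unique/multi-hit mapping
    classification, a five-criterion high-confidence variant-site filter
    (depth outliers, strand coverage, indel-adjacent masking, per-allele
    strand bias, read-end artifacts) producing callable target regions and
    filtered SNP/indel calls, pairwise strain divergence statistics over
    effective (jointly callable) genome length, allele-sharing-distance
    matrices with UPGMA dendrograms, strain pseudo-sequence extraction from
    reference plus variants, Bonferroni-corrected pairwise phenotype
    significance matrices, and a synthetic-data generator with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    IRanges,
    S4Vectors,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    rtracklayer,
    Rsamtools,
    ape,
    vcfR,
    data.table
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
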