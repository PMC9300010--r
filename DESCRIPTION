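Package: reedwgd
Title: Detecting and Dating Lineage-Specific Whole-Genome Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers and dates lineage-specific whole-genome duplication (WGD)
    events from gene-level evidence: protein-similarity homology search with
    reciprocal best hits and orthologue-group clustering, colinear synteny-block
    detection by anchor chaining, synonymous divergence (Ks) at four-fold
    degenerate sites with kernel-density peak dating, orthologue copy-number
    ratio (R_CN) classification of conserved versus duplicated gene groups,
    hypergeometric tests for biased functional retention of duplicates, and a
    functional-ploidy test based on nonreference allele frequencies of
    short-read counts. Includes a genome-evolution simulator that generates
    multi-species gene complements descended from an ancestral gene order via
    speciations at chosen synonymous-divergence depths, a branch-specific WGD
    with category-biased duplicate retention, gene-order rearrangements, and
    binomial read sampling over heterozygous sites, so every inference step is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
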