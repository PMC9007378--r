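Package: mtburden
Title: Mitochondrial Heteroplasmy Burden Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality control, classification and disease-association analysis of
    mitochondrial DNA (mtDNA) heteroplasmic single-nucleotide variants called
    against the revised Cambridge Reference Sequence (rCRS). Implements the
    variant- and sample-level quality-control cascade used in deep mtDNA
    sequencing studies (depth, strand support, homopolymer masking, cohort
    prevalence, reference-panel concordance, and a coefficient-of-variation
    filter for nuclear-mitochondrial (NUMT) pseudo-heteroplasmies),
    heteroplasmy classification and per-individual burden aggregation,
    negative binomial burden regression with covariates, SKAT-O style region
    burden tests over gene loci and sliding tiles with a permutation oracle,
    and strand- and replication-arc-resolved trinucleotide mutational
    signatures with two-proportions asymmetry tests. A synthetic cohort
    generator with truth labels makes every stage testable without access to
    individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
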