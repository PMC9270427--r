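Package: cryptburden
Title: Somatic Mutation Burden, Phylogeny and Signature Analysis for Clonal
    Normal-Tissue Whole Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome sequencing of laser-capture
    microdissected clonal units of normal tissue (e.g. intestinal crypts),
    with an emphasis on cohorts carrying germline base-excision-repair
    defects such as biallelic MUTYH mutations. Classifies pileup variants
    into germline and somatic calls using an aggregate exact binomial test
    and beta-binomial overdispersion; corrects per-sample mutation burdens
    for calling sensitivity from coverage and clonality; reconstructs
    per-patient crypt phylogenies by exact maximum parsimony and assigns
    mutations to branches by maximum likelihood; extracts mutational
    signatures de novo by KL non-negative matrix factorisation, decomposes
    them into reference signatures by expectation maximisation and refits
    exposures with pruning; estimates genotype-specific mutation rates per
    year with linear mixed-effects models; normalises duplex-sequencing
    burdens onto genomic trinucleotide frequencies; and classifies candidate
    cancer driver mutations by rule. A seeded synthetic-cohort generator
    emulating clonal VAF structure, shared lineage variants and
    signature-mixture mutation spectra makes every stage testable without
    access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
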