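Package: karyoevolve
Title: Sex Chromosome Evolution from Coverage, Synteny and Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers sex-linked scaffolds from normalized female/male
    sequencing depth, reconstructs ancestral beetle linkage groups
    (Stevens elements) from 1:1 ortholog tables, counts chromosome
    fusion and fission events, locates ancestral-X/neo-X breakpoints by
    changepoint analysis of coverage ratios, and tests for dosage
    compensation and gonadal sex-biased gene enrichment on neo-sex
    chromosomes. Includes a synthetic-data generator that simulates
    karyotype histories along a phylogeny, sexed coverage tracks,
    ortholog tables, and tissue expression matrices with known ground
    truth, so the whole inference chain can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, Coverage, Phylogenetics, GeneExpression, Software
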