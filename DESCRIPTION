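Package: parecrit
Title: Data-Driven Inference of Plant miRNA Targeting Criteria from
    Paired Small RNA and Degradome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers plant miRNA-mRNA targeting criteria directly from
    paired small RNA and degradome (PARE) sequencing data instead of
    relying on fixed Allen-style rules. Provides degradome cleavage-peak
    categorization (categories 0-3, high/low confidence), position-weighted
    miRNA-mRNA duplex alignment and scoring with G:U wobbles and bulges, a
    nearest-neighbor minimum-free-energy ratio, retain-rate based criteria
    inference with a sensitivity/precision sweep, evaluation against
    experimentally validated interactions, position-specific property
    statistics (offset chi-square, Fisher exact, subsampled
    Kolmogorov-Smirnov), and a seeded synthetic-fixture generator with
    planted cleavage signals for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
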