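Package: varobs
Title: Local Observation Database for Genomic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maintains a continuously updatable local database of variant
    observations from family-based sequencing cases. Single nucleotide
    variants and small indels are counted once per family under a genotype
    quality gate; structural variants are clustered on the fly by breakpoint
    proximity using padded endpoint intervals with running-mean positions.
    Observation counts and local frequencies can be exported as a VCF or
    used to annotate a query VCF directly, so that rare-disease analyses
    can filter out locally common variation and platform artifacts. Includes
    a synthetic family-cohort generator and a harness for studying how
    filtering efficiency scales with database size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    vcfR,
    yaml,
    optparse,
    rlang,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
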