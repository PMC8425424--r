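Package: cupScan
Title: Conversion-Unstable Positions Between Genome Builds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies base-pair positions that are unstable when converting
    coordinates between genome reference builds (for example GRCh37 and
    GRCh38) from the chain files alone. Every position of the source build is
    lifted to the target build and back again, and classified as stable or as
    one of five conversion-unstable position (CUP) categories: first-conversion
    failure, chromosome jump on the first conversion, second-conversion
    failure, chromosome jump on the return, or position jump on the return.
    Includes an exact interval-algebra scanner equivalent to the per-base
    definition, overlap statistics against assembly annotation tracks (gaps,
    contig differences, segmental duplications), a VCF conversion workflow with
    the two reference-allele mismatch dialects used by common liftover tools,
    pre-exclusion filtering of variants at unstable positions, discordance
    metrics, and a generator of paired synthetic builds with exact chain files
    and analytically known per-base truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
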