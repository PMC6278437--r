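Package: methrestore
Title: Integrative Methylation-Expression Restoration-Pattern Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed differential-methylation calling from bisulfite
    cytosine count tables, genomic-feature annotation, negative-binomial
    differential expression, and integration of the two layers under a
    three-condition (control / disease / treatment) design. Regions whose
    methylation change under disease is reversed by treatment
    (hyper/hypo or hypo/hyper) are matched to genes whose expression shows
    the mirrored restoration (down/up or up/down) and an inverse Spearman
    correlation, yielding Pattern A / Pattern B epigenetically regulated
    genes. Includes a seeded beta-binomial / negative-binomial simulator
    with planted restoration signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
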