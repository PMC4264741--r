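Package: svcallr
Title: Structural Variant Discovery from Paired-End and Mate-Pair Read Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects structural variants (deletions, tandem duplications,
    inversions, insertions and translocations) from coordinate-sorted
    paired-end or mate-pair alignments. Discordant read pairs are identified
    against a robust insert-size model, grouped by a streaming hard-clustering
    engine whose similarity window is twice the insert-size standard
    deviation, and typed from their orientation/insert-size signature.
    A windowed depth-of-coverage ratio analysis against a reference sample
    provides complementary copy-number evidence; local-realignment rescue and
    repeat-track overlap filters suppress mapping artifacts; evidence is
    merged into unified calls written as VCF, BEDPE and bedGraph. A built-in
    read-pair simulator with truth manifests makes the whole pipeline
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    SummarizedExperiment,
    VariantAnnotation,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
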