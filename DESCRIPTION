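Package: ocre
Title: Open-Chromatin Regulatory Element Discovery from Differential
    Accessibility and Combinatorial Transcription-Factor Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls candidate tissue-specific enhancers by combining
    differential chromatin accessibility with transcription-factor
    occupancy. Paired-end ATAC-seq fragments are reconstructed,
    deduplicated and turned into coverage tracks; differential
    accessibility between two conditions is detected with a
    sliding-window G-test and Benjamini-Hochberg correction, followed by
    a promoter-exclusion filter. Peak sets for three transcription-factor
    ChIP experiments are blacklist-filtered and clustered into the seven
    combinatorial binding categories; single-bp peak summits are
    intersected with differentially accessible regions to define
    candidate enhancers, which are then assigned target genes by a
    nearest-neighbour rule and summarised per gene as UpSet-style
    category combinations. A fully parameterised synthetic-data
    generator (toy genomes, fragment libraries with planted differential
    regions, peak sets with known combinatorial structure, expression
    tables with planted condition-specific genes) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
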