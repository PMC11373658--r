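Package: palmannot
Title: Consolidation, Evidence Classification and Comparative Validation of
    Oil Palm Genome Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for plant genome annotation built around
    the oil palm (Elaeis) reference genomes. Merges two gene-prediction sets
    by coordinate rules, removes candidate long non-coding RNAs by a
    coding-potential/homology consensus, integrates CAGE, RNA-Seq and
    homology evidence into a six-class gene-model classification with
    representative-isoform selection, profiles cytosine methylation around
    translation start and end sites per class, correlates gene and repeat
    densities in genomic windows, filters interspecific structural variants,
    and designs junction-diagnostic PCR primer schemes validated by
    electronic PCR. Ships a synthetic-data generator with machine-readable
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    rlang,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tibble,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
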