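Package: phasitrack
Title: Phased Small RNA Cluster Discovery, TAS Locus Characterization, and
    Degradome Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for genome-wide analysis of plant secondary small
    RNAs: windowed negative-binomial differential abundance of 21-, 22-,
    and 24-nt siRNAs between two genotypes, discovery of phased siRNA
    clusters with a phasing score, detection and characterization of
    two-hit TAS loci (dual miR390-class trigger sites setting the 21-nt
    register), small RNA target scoring with the Allen penalty scheme, and
    validation of predicted cleavage sites against PARE degradome 5'-end
    signatures. Includes a synthetic data generator with full ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    edgeR,
    GenomicRanges,
    IRanges,
    rlang,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
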