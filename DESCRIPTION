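Package: mutscreen
Title: Comparative Mutagenesis Screen Analysis for Beneficial Mutational Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for forward-genetic screens that measure the
    distribution of beneficial mutational effects for chemical-stress
    resistance in yeast. Converts colony-size plate grids into dose-response
    resistance scores (trapezoid AUC and delta-AUC against the ancestor),
    flags physiological escapees, normalizes plate edge effects by layer,
    estimates phenotypic mutation rates and screen saturation from plating
    counts, applies a six-rule site filter to multi-strain genotype matrices,
    tests gene-level mutation enrichment and chromosome-aneuploidy enrichment
    against Monte-Carlo null distributions, calls whole-chromosome copy
    numbers and diploidization from windowed sequencing depth, estimates
    focal-locus copy number, and searches for short flanking inverted
    repeats. Includes a synthetic-data generator with planted ground truth so
    the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    VariantAnnotation
Config/testthat/edition: 3
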