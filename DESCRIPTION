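Package: genomeflux
Title: Genome-in-Flux Analysis of Whole-Genome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-based small-variant and structural-variant calling
    from whole-genome alignment coordinate tables, private-variant
    polarization against an outgroup, AT-GC substitution spectra with CpG
    masking, odds-ratio and equilibrium-GC estimation, fixed-window
    isochore and ancestral/current chromosome-state annotation, NUMT and
    interstitial-telomere scanning, and the accompanying statistical
    layer. A fully parameterized diploid genome-evolution simulator with
    planted-event truth tables makes every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
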