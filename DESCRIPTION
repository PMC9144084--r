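Package: mtmosaic
Title: Detection of Interspecific Mitochondrial Genome Recombination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting interspecific recombination in mitochondrial
    genome alignments. Implements sliding-window nucleotide diversity and
    divergence profiles, detection of high-divergence (HD) regions, the
    pairwise homoplasy index (PHI) permutation test, MaxChi-style breakpoint
    localization, triplet closer-parent scanning, mosaic-genome annotation
    with recency classification of transferred fragments, and a calibrated
    simulator of mosaic mitochondrial genomes for validating the whole
    pipeline.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
LinkingTo: Rcpp
Encoding: UTF-8
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
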