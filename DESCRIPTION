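Package: sweepsig
Title: Selective Sweep Detection from Multilocus Polymorphism and Divergence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infrastructure for detecting recent selective sweeps in small
    multigene regions from phased haplotype alignments with an outgroup.
    Implements nucleotide diversity by site class (total, nonsynonymous,
    synonymous, silent), sliding-window diversity tracks, site frequency
    spectrum construction with outgroup polarization, Tajima's D and
    normalized Fay-Wu H with coalescent significance, pairwise and
    maximum-likelihood HKA tests, a composite-likelihood-ratio sweep scan
    built on a sweep-transformed background spectrum, the omega linkage
    disequilibrium scan, McDonald-Kreitman tests and a counting dN/dS
    estimator, a Hudson-style neutral coalescent simulator (with fixed-S
    conditioning and recombination) for empirical null distributions, and a
    synthetic-data generator that emulates a multi-population resequencing
    study of a ~17-kb seven-gene region.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, PopulationGenetics, Coverage, Sequencing
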