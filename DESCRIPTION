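Package: heliscan
Title: Structure-Based Annotation and Comparative Analysis of Helitron
    Transposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structure-based discovery and comparative analysis of Helitron
    transposable elements. Detects the canonical Helitron hallmarks (5' TC and
    3' CTRR termini, the GC-rich subterminal hairpin, the A^T insertion-site
    preference), runs k-mer seeded homology searches with hit merging and
    paired-termini mother-element scanning, segments internal tandem-repeat
    blocs with per-bloc GC content, clusters element copies and builds
    majority-rule consensus sequences, classifies element families by terminal
    identity, and types presence/absence polymorphisms between two genomes
    (clean insertions versus the three excision-footprint classes) with an
    extrapolation of family-wide transposition activity. A fully seeded
    synthetic-genome generator with planted truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
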