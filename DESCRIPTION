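Package: sdrscan
Title: Structural Annotation of Tyrosine-Recombinase Retrotransposon Copies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes genomic copies of VIPER/TATE-like tyrosine-recombinase
    (DIRS-order) retrotransposons. Provides six-frame ORF discovery with
    role assignment (gag-like, YR, RT/RH) and CH-box motif scanning, de novo
    detection of split direct repeats (SDRs) by self-comparison with
    seed-and-extend maximal-segment search, terminal-repeat labeling and
    architecture typing, element boundary calling, per-copy status
    classification (putative autonomous, potentially encoding, degenerate,
    inconclusive, SIRE-like remnant), and a divergence toolkit with
    confident-region identity masking, Poisson-corrected distances,
    neighbor-joining trees and a same-species monophyletic redundancy filter.
    A synthetic element generator plants elements with full ground truth so
    every stage of the pipeline is verifiable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
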