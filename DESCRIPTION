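Package: zfscan
Title: Z-DNA-Forming Site Discovery from Replicated ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to identify Z-DNA-forming sites (ZFSs) from replicated
    ChIP-Seq experiments with a Z-DNA-binding protein probe, and to
    characterize them. Implements a zipper-model calculation of B-to-Z
    transition energetics that translates the transition free energy of a
    DNA segment into the minimal negative superhelical density required to
    form Z-DNA, sequence scanning for Z-DNA-forming regions (ZDRs) at a
    superhelical density cutoff, sliding-window superhelicity profiles, a
    window-based Poisson peak caller, irreproducible discovery rate (IDR)
    analysis with pseudoreplicates and the maximum-cutoff selection rule,
    blacklist filtering, genomic region classification with length-matched
    random-peak null models and proportion tests, and transcription
    association analyses (RPKM expression groups, TSS metaprofiles,
    enrichment heatmaps, overlap and rank tests). A synthetic-data
    generator emulates replicated ChIP-Seq over a toy genome with planted
    Z-DNA-forming repeats and known truth, so the whole pipeline can be
    exercised and scored end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
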