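Package: plvscan
Title: Detection of Endogenous Polinton-Like Viruses and Virophages in
    Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects complete endogenous polinton-like viruses (PLVs) and
    virophages in eukaryotic genome assemblies by combining terminal
    inverted repeat (TIR) discovery, windowed GC-content segmentation,
    and hallmark-gene evidence; calls target site duplications (TSDs)
    from element flanks by exhaustive sliding/padding alignment; computes
    per-genome expansion statistics; and clusters elements by gene
    sharing with bipartite (Barber) modularity community detection.
    Includes a synthetic-genome generator that plants TIR-bounded,
    GC-shifted, TSD-flanked elements with machine-readable ground truth,
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    tibble,
    dplyr,
    readr,
    rlang,
    withr,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
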