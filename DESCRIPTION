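Package: motiflm
Title: Short-Context Masked DNA Language Models with a Motif-Scale Fourier Prior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and interrogating short-context (350 bp) masked
    language models of regulatory DNA. The masked-reconstruction objective is
    augmented with a frequency-domain prior that concentrates the per-base
    likelihood landscape on motif-scale (6-20 bp) variation, down-weighting both
    noise-like high-frequency structure and repeat-like low-frequency structure.
    Includes corpus construction from FASTA/BED with chromosome-based splits and
    repeat-aware loss masking, a synthetic motif-planted corpus generator with
    labelled variant sets, zero-shot likelihood reconstruction and nucleotide
    dependency maps, log-likelihood-ratio variant scoring with an evaluation
    protocol, per-base embedding extraction with chunked tiling for long inputs,
    and oracle-guided beam-search sequence design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    pROC,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
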