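Package: macropan
Title: Discovery Analysis for Chemically Modified Phage-Display Macrocycle Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, tested pipeline for the computational discovery of
    target-binding macrocyclic peptides from phage-displayed SXCX(n)C libraries.
    Covers the library architecture model (theoretical diversity, translation,
    architecture classification), a ground-truth-known synthetic selection and
    paired-end FASTQ simulator, read deconvolution (quality filtering, barcode
    demultiplexing, priming-region matching with at most one substitution,
    zero-mismatch forward-reverse agreement), differential-enrichment hit
    calling with an exact conditional binomial test, motif analysis
    (position-frequency matrices, dipeptide enrichment, Hamming-distance
    family clustering with consensus calling), and quantitative binding models
    for the downstream validation assays: exact ligand-depletion fraction
    bound, fluorescence-polarization K_D fitting, 19F NMR signal-suppression
    AC50 estimation, and alanine-scan delta-delta-G analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    minpack.lm,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
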