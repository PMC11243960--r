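Package: fluoromics
Title: Chlorophyll Fluorescence Phenotyping and Multi-Omics Screening
    for UV-B Stress Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of fast chlorophyll fluorescence (OJIP) transients
    with JIP-test parameter derivation and K-band (delta-Wk) difference
    statistics, pulse-amplitude-modulated (PAM) quenching analysis with
    rapid-light-curve fitting (alpha, ETRmax, Ek), rule-based differential
    screening of transcript, protein and metabolite tables (fold change,
    Welch tests, PLS-VIP, Benjamini-Hochberg), and transcription-factor to
    gene to metabolite integration via Pearson correlation networks and
    Mantel permutation tests.  Includes seeded synthetic-data generators
    for all three input kinds so every stage has a parameter-recovery
    test surface, plus delimited-text readers/writers for instrument-style
    tables and a small pipeline/CLI layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    mixOmics,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
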