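Package: picsr
Title: Protease Cleavage-Site Specificity Profiling from Proteome-Derived
    Peptide Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling protease cleavage-site specificity with
    proteome-derived peptide libraries (the PICS strategy). Builds in-silico
    GluC, chymotryptic or tryptic peptide libraries from a proteome, maps
    identified prime-side cleavage products back to the proteome to
    reconstruct full P6-P6' cleavage windows with isoform-aware ambiguity
    masking, summarises windows as positional occurrence heat maps and
    background-normalised enrichment profiles with per-cell significance
    (iceLogo-style), derives subsite position weight matrices for scoring
    candidate substrate windows, and performs modification-aware peptide
    mass calculations for MALDI cleavage assays. A seeded simulator
    generates multi-isoform proteomes and protease assays with planted
    subsite preferences, detection loss and decoy contamination so the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
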