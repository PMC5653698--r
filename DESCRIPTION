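Package: siptrflp
Title: Stable-Isotope Probing Analysis of T-RFLP Community Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA stable-isotope probing (DNA-SIP) experiments read
    out by terminal restriction fragment length polymorphism (T-RFLP).
    Converts CsCl gradient refractive indices to buoyant densities, predicts
    terminal restriction fragments by in-silico digestion of 16S rRNA gene
    sequences, scales T-RF fluorescence proportions by qPCR 16S copy numbers
    into per-fragment buoyant-density distributions, detects labeled-versus-
    unlabeled density shifts, affiliates shifted fragments to clone sequences,
    and summarises OTU community tables and VOC degradation time series. A
    synthetic-data generator emulates the gradient, electropherogram, qPCR
    and degradation data so the full pipeline is testable without downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
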