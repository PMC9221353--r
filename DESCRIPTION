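Package: nkscreen
Title: Analysis of High-Throughput Luciferase-Release NK-Cell Cytotoxicity Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing plate-based natural killer (NK) cell
    cytotoxicity screens that use a luciferase-release readout. Implements the
    96-well screen plate model (compounds in columns 2-11, vehicle and
    positive controls in columns 1 and 12), percent specific lysis, per-plate
    Z'-factor quality control, fold-change normalisation over in-plate DMSO
    controls, dual-replicate hit calling with a target-alone toxicity
    counter-screen, exact rank-sum dose-response validation with a
    minimum-effective-dose call, and a generative simulator of the full screen
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
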