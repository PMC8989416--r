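Package: peptivax
Title: Immunopeptidome-Based Selection of Tumor Peptide Vaccine Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational arm of an MHC class I
    immunopeptidomics-to-vaccine workflow: ligandome quality control (length
    filtering, peptide-to-protein mapping, position-weight-matrix scoring and
    percentile-rank binder calibration), Gibbs-sampling motif deconvolution
    with Kullback-Leibler fitness, dual-contrast expression-based
    tumor-associated-antigen prioritization, pathogen-mimicry scoring of
    candidate epitopes, ELISpot immunogenicity gating, and surface plasmon
    resonance quantitation of peptides per viral particle. Includes a
    seeded synthetic-data generator with planted ground truth so every stage
    is testable without external downloads.
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
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
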