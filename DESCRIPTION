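Package: umiconsensus
Title: Simulation and Barcode-Consensus Error Correction for UMI Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying background error in barcoded (unique molecular
    identifier, UMI) amplicon sequencing. Provides a generative simulator of
    barcoded library construction (fidelity-scaled polymerase errors over a
    short barcoding PCR, per-family amplification bias in the adapter PCR,
    uniform sequencer substitution noise) with full ground-truth lineage
    tracking; structural read validation and primer-anchored banded alignment;
    barcode-family grouping and family-size-dependent consensus calling; raw
    versus consensus error profiles, substitution spectra and rank-based
    comparison statistics; and detection of low-frequency variants against the
    panel-wide background error distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
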