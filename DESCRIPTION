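Package: casoform
Title: Proteoform and PTM Site-Occupancy Profiling of Human Milk Beta-Casein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Protein-specific profiling of phosphorylation and O-glycosylation
    for human milk beta-casein from mass-spectrometry derived tables.
    Enumerates the combinatorial phospho/O-glycoproteoform library of the
    mature chain with theoretical monoisotopic and average masses, annotates
    deconvoluted intact-mass features by proteoform-spectrum-match tables and
    by theoretical mass matching with retention-time gating, curates bottom-up
    peptide-spectrum matches with score and localization thresholds, and
    quantifies per-site longitudinal modification occupancy by PSM counting
    with MS1 precursor-area cross-validation. Includes seeded generators for
    ground-truthed synthetic PSM, intact-feature and peptidoform-area tables
    so the whole pipeline can be exercised and validated without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
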