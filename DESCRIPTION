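Package: ms2curate
Title: Automated Curation of Tandem Mass Spectral Reference Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns raw data-dependent LC-HRMS/MS acquisitions of
    (semi)purified natural-product samples into quality-filtered,
    formula-annotated, mass-recalibrated reference spectra exported as
    MassBank-format records. Implements targeted MS2 extraction against a
    compound metadata table, tiered-tolerance fragment subformula
    annotation, a robust mass-error recalibration curve fitted from
    uniquely assigned intense fragments, collision-gas (N2/O) adduct
    checking, cross-spectrum multiplicity filtering, and an orthogonal
    quality filter based on the correlation of fragment and precursor
    extracted-ion chromatograms with an automatically selected,
    F-score-maximizing cutoff. Ships a ground-truthed synthetic
    acquisition generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    mzR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
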