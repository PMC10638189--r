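Package: gagnre
Title: Glycosaminoglycan Non-Reducing-End Profiling for Mucopolysaccharidosis Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for LC-MS1/MS2 analysis of lyase-depolymerized, 2-aminobenzamide
    (2-AB) labeled chondroitin/dermatan and heparan sulfate saccharides. Builds the
    theoretical ion catalog (charge states, di-n-butylamine adducts, in-source
    sulfate-loss products) for internal disaccharides and saturated non-reducing-end
    (NRE) mono- to trisaccharides, matches deconvoluted MS1 feature tables to it
    within a ppm tolerance, annotates negative-mode MS2 spectra with diagnostic
    fragment ions for positional and epimeric isomer assignment, computes
    relative-abundance and NRE/disaccharide ratio statistics with labeling-efficiency
    QC, and evaluates rule-based urinary biomarker panels for mucopolysaccharidosis
    (MPS) subtypes. A seeded synthetic-data generator emulates the statistical
    structure of patient and control samples so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
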