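Package: oxlipidr
Title: Targeted Identification and Profiling of Oxidized Membrane Lipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for targeted identification and relative quantification of
    oxidized diacyl membrane lipids (ox-PC, ox-PE, ox-PG, ox-PI, ox-PS, ox-MGDG,
    ox-DGDG) from negative-mode LC-MS/MS data. Generates an in-silico candidate
    library of oxylipin-containing glycerophospholipids and galactolipids,
    computes monoisotopic precursor and carboxylate-fragment m/z values,
    matches them against MS1 feature tables within ppm tolerances, verifies
    hits by MS/MS fragment presence and retention-time elution-pattern rules,
    exports scheduled-MRM transition lists, integrates fragment extracted-ion
    chromatograms with class-specific summation rules, normalizes by internal
    standard and sample weight, filters by pooled-QC coefficient of variation,
    and performs per-lipid and per-class differential abundance analysis with
    Benjamini-Hochberg correction. Includes a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mzR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
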