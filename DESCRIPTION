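Package: pmdda
Title: Paired-Mass-Distance Dependent Precursor Selection for Targeted MS/MS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for turning an untargeted LC-HRMS MS1 feature table into a
    targeted MS/MS acquisition plan. Features are quality-filtered (retention
    time range, blank fold change, replicate RSD), redundant ions (adducts,
    isotopologues, neutral losses) are collapsed into pseudo-spectra by
    frequency analysis of paired mass distances, one precursor ion is elected
    per putative compound, and precursors are scheduled into multiple targeted
    injections under retention-time density constraints. Additional tools link
    features across ionization polarities, merge repeated MS2 scans into
    consensus spectra exported as MGF, match precursors against known-compound
    mass lists, and simulate ground-truth datasets for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    mzR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
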