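Package: phosquant
Title: Fragment-Ion Peak-Area Label-Free Quantification of Phosphopeptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Label-free relative quantification of protein phosphorylation
    from LC-MS/MS runs using extracted ion chromatograms of MS2 fragment
    ions (pseudo-SRM). Provides a monoisotopic mass engine for modified
    tryptic peptides and their b/y fragment ions (including phosphate
    neutral losses), mzML input/output built on mzR, chromatogram
    extraction and peak-area integration at precursor (ppm) and fragment
    (Da) tolerances, Ascore-style phosphosite localization by cumulative
    binomial scoring of site-determining ions, normalization to endogenous
    unphosphorylated internal-standard peptides, control-relative fold
    changes with paired t-tests, and a seeded simulator of paired
    control/treated data-dependent acquisition runs with known ground-truth
    fold changes for end-to-end validation. Ships the PPP1R12B
    phosphopeptide panel and published normalized peak areas as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    mzR,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    rlang,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
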