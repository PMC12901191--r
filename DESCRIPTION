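Package: licoquant
Title: Targeted GC-MS/MS Quantification, Bioanalytical Validation and
    Brain Pharmacokinetics of Licochalcone A
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the complete quantitative workflow behind a targeted
    GC-MS/MS assay of the flavonoid licochalcone A in mouse brain tissue:
    trimethylsilyl-derivative mass arithmetic and electron-impact fragment
    annotation, oven-program timing, Kovats retention indices, multiple
    reaction monitoring (MRM) transition selection and time-segmented
    acquisition schedules, chromatographic peak detection and integration,
    FDA-style qualitative identity confirmation, ICH M10 bioanalytical method
    validation statistics (linearity, LOD/LOQ, precision and accuracy,
    extraction recovery, matrix effect), quantification with homogenate to
    tissue unit conversion, non-compartmental pharmacokinetic analysis of
    sparse destructive-sampling concentration-time data, and rodent memory
    scores (novel-object discrimination ratio, Y-maze spontaneous
    alternation).  A synthetic-data module generates every input with known
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
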