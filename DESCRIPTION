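Package: wingpol
Title: Quantification of Planar Polarity, Endosomal Puncta and FRAP Kinetics in Mosaic Epithelia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification and statistical pipeline for clonal (mosaic)
    analysis of planar cell polarity in the Drosophila pupal wing. Computes
    per-cell polarity magnitude (maximum asymmetry ratio) and axial angle from
    junctional fluorescence, mutant-to-wild-type membrane intensity ratios,
    area-fraction-calibrated detection of endosomal puncta, extracellular-label
    internalization time courses, and one- or two-phase exponential FRAP
    recovery fits compared with extra-sum-of-squares F tests. Includes a
    synthetic-data generator that emulates polarized epithelial wings, puncta
    fields, internalization series and FRAP traces so every pipeline stage is
    testable without raw microscopy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    multcomp,
    stats,
    tiff,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
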