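Package: fcmscreen
Title: Untargeted GC-EI-HRMS Screening and TTC Risk Assessment of Food
    Contact Material Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the automated tentative identification and risk
    assessment of unknown substances (intentionally and non-intentionally
    added, IAS/NIAS) in plastic food contact material extracts analysed by
    gas chromatography with electron-ionization high-resolution mass
    spectrometry. Implements NIST-style spectral library matching with a
    composite score combining a Stein-Scott weighted dot product (search
    index, SI) with a high-resolution filtering (HRF) score based on
    exact-mass subformula annotation of fragment ions; van den Dool-Kratz
    retention-index calibration against n-alkane ladders; a restrictive
    identification gate (total score, fragment mass accuracy, retention
    index difference); internal-standard response-factor semi-quantification
    and migration estimation; and a threshold-of-toxicological-concern (TTC)
    screen comparing estimated daily intakes against Cramer-class tolerable
    daily intakes and specific migration limits. Includes a synthetic-data
    generator for hermetic end-to-end validation and a bundled reference
    dataset from a screen of post-consumer recycled LDPE film.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
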