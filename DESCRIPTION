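Package: nanoaroma
Title: Odor-Value Perfumery Radar and Power-Law Release Kinetics for
    Nanoencapsulated Essential Oils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for nanoencapsulated essential-oil studies:
    compound property registries with ranked olfactory families, GC-MS
    composition handling and external-standard calibration, encapsulation
    efficiency and DPPH radical-scavenging assay formulas, ideal
    (Raoult-law) headspace concentration prediction, odor-value scoring
    and normalized eight-family perfumery radar profiles, and
    Korsmeyer-Peppas power-law release fitting by Nelder-Mead least
    squares with transport-mechanism classification. Includes
    seed-reproducible synthetic-data generators for release curves,
    composition tables, and antioxidant assay series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
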