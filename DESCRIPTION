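Package: msipair
Title: Ion-Pairing Dication Adduct Annotation for Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recovers negatively charged metabolites acquired in positive
    ionization mode mass spectrometry imaging (MSI) through dicationic
    ion-pairing adducts. Provides exact monoisotopic mass and isotope-pattern
    algebra for elemental formulas, a model of the
    1,5-pentanediyl-bis(1-butylpyrrolidinium) dication reagent (adduct m/z
    prediction, the 324.3494 Da mass shift, and glycerophospholipid
    headgroup fragment prediction for MS/MS validation), imzML-backed
    pixel-grid processing with tissue-specific peak finding (ppm-tolerance
    clustering and on/off-tissue abundance ratio filtering), mass-shift
    library annotation with carbon-count spectral-accuracy checks,
    cross-polarity coverage reporting, and ion images. A seeded synthetic
    data generator emulates paired negative / positive / adducted-positive
    acquisitions with full ground truth so that every pipeline stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
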