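Package: aporphiner
Title: Annotation of Aporphine Alkaloids from High-Resolution LC-MS/MS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the targeted identification of aporphine alkaloids from
    high-resolution tandem mass spectrometry data. Provides exact monoisotopic
    mass arithmetic over elemental compositions, accurate-mass molecular formula
    decomposition under ppm tolerances and element-count bounds, a curated
    reference library of aporphine alkaloids with scaffold/substituent candidate
    enumeration for parallel reaction monitoring (PRM) inclusion lists, a
    neutral-loss and diagnostic-fragment-ion rulebase that classifies the
    nitrogen substitution type (quaternary, tertiary, secondary) of a spectrum,
    and an end-to-end annotation pipeline over MGF or mzML peak lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mzR,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
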