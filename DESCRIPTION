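Package: nitroquant
Title: Stable-Isotope-Coded Nitrotyrosine Detection and Relative
    Quantitation from High-Resolution MS/MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and relatively quantifies tyrosine-nitrated peptides
    from centroided LC-MS/MS runs using the light/heavy nitrotyrosine
    immonium reporter-ion pair (m/z 181.0608 / 182.0578) produced by
    nitration with natural-abundance versus 15N-labeled peroxynitrite.
    Provides elemental-composition and fragment-ion arithmetic, exact
    isotope fine-structure computation with Gaussian FWHM profile
    synthesis and minimum-resolution determination for near-isobaric
    doublets, mzML reading and writing, a seeded data-dependent
    acquisition simulator for co-isolated light/heavy nitropeptide pairs,
    per-scan reporter-ratio quantitation with isotopic-interference
    correction, and internal-standard normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mzR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
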