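Package: clamtrace
Title: Stepwise Geographical Origin Authentication of Manila Clams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for authenticating the geographical origin of the Manila
    clam (Ruditapes philippinarum) from stable-isotope and fatty-acid
    measurements. Implements delta-notation isotope conversions, fatty-acid
    profile feature engineering (SFA/MUFA/PUFA classes, diet biomarker sums,
    DHA/EPA and PUFA/SFA ratios), min-max feature scaling, linear
    discriminant analysis with leave-one-out cross-validation written from
    first principles, and a tiered cascade that escalates unauthenticated
    samples from cheap bulk-isotope measurements to fatty-acid profiles and
    compound-specific carbon isotopes of individual fatty acids. Ships
    site-level reference fixtures and a seeded synthetic-sample generator so
    the whole pipeline runs without access to raw per-sample assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
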