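Package: qmarker
Title: Spectrum-Effect Quality-Marker Discovery for Herbal Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric discovery of bioactive quality markers from paired
    chromatographic peak-area and bioassay tables. Implements grey relational
    analysis (Deng's degree with a configurable distinguishing coefficient),
    NIPALS partial least squares regression with cross-validated component
    selection, variable-importance-in-projection (VIP) scores, standardized
    coefficients and Y-permutation validation, rule-based candidate screening
    (VIP and coefficient thresholds with across-assay unions), bioassay
    arithmetic (DPPH radical scavenging, FRAP ferrous equivalents,
    NO-inhibition rates and four-parameter-logistic IC50 estimation), and a
    drug-likeness admission stage (Lipinski, Ghose, Veber, Egan and Muegge
    filters plus a gastrointestinal-absorption ellipse classifier with a
    high-content override). A synthetic-data generator with known ground-truth
    active compounds makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    yaml
Config/testthat/edition: 3
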