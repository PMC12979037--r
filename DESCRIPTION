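Package: tracescore
Title: Stable Isotope Tracing Analysis via Metabolite Labeling Scores
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for steady-state stable isotope tracing
    experiments measured by LC-MS. Corrects raw isotopologue intensity
    vectors for natural isotope abundance (closed-form binomial /
    convolution correction matrices solved by non-negative least squares),
    computes fractional enrichment and total labeling, derives Metabolite
    Labeling Scores normalized to a reference metabolite (glutamate by
    default), compares scores between model systems by volcano-style
    differential analysis, and performs permutation-based quantitative
    metabolite set enrichment analysis. Ships a 15N2-glutamine label
    propagation simulator over small nitrogen-transfer networks so the
    whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
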