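Package: pcruq
Title: Uncertainty Quantification for Strand-Specific PCR Fluorescence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models real-time PCR (qPCR and RT-qPCR) as a two-type
    Galton-Watson branching process that distinguishes the two complementary
    DNA strands and their amplification efficiencies. Provides exact and
    asymptotic first and second moments of strand counts, a Monte-Carlo
    simulator of the stochastic amplification model, a Beer's-law analog
    model of hydrolysis-probe fluorescence with molar-fluorescence
    calibration from control plates, and analytic limit-of-detection
    calculations for double-stranded DNA and single-stranded RNA inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'pcruq-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'input.R'
    'efficiency.R'
    'moments.R'
    'plates-io.R'
    'fluorescence.R'
    'lod.R'
    'simulate.R'
    'synthetic.R'
    'cli.R'
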