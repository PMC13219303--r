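Package: carescreen
Title: Careless-Responding Screening and Its Psychometric Consequences
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates Likert survey data with known careless-responding
    contamination, flags careless respondents with instructed-item,
    longstring and even-odd consistency indicators, runs a parallel
    unscreened-versus-screened psychometric battery (Cronbach's alpha with
    Feldt intervals, McDonald's omega via a higher-order Schmid-Leiman
    decomposition, maximum-likelihood confirmatory factor analysis,
    multigroup measurement invariance), quantifies screening impact with
    nested-sample permutation tests, Fisher z / Cohen's q correlation
    comparisons and effect sizes, and ranks item vulnerability with the
    Composite Sensitivity Index (CSI) and its z-scored variant.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
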