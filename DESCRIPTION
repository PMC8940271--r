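Package: photopheno
Title: Biophysical Phenotyping of Photosynthesis from Fluorescence and
    Absorbance Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to derive photosynthetic phenotypes from raw
    spectroscopy time series: PAM chlorophyll-fluorescence quenching
    analysis (NPQ, PhiPSII, 1-qL, qT, NPQ induction/relaxation
    decomposition), electrochromic-shift (ECS) analysis of
    per-photosystem photochemical rates, PSII/PSI stoichiometry and the
    cyclic electron flow fraction, time-correlated single photon
    counting (TCSPC) decay fitting with fixed lifetimes and the PSI
    chlorophyll share, fast fluorescence induction (Vj) and
    plastoquinone reoxidation kinetics, DCMU-induction functional
    antenna size, chlorophyll a/b quantification from acetone-extract
    absorbances, and normality-gated group comparisons plus
    Poisson/linear models for grana morphometry. A synthetic trace
    generator with known ground truth stands in for the instruments so
    that every derivation can be tested by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    withr,
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
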