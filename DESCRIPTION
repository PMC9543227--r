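Package: longconn
Title: Longitudinal Functional Brain Network Analysis from EEG Source
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal analysis of frequency-band-specific
    functional brain networks reconstructed from EEG: weighted
    minimum-norm source estimation on a supplied leadfield, zero-phase
    band filtering, phase-locking-value (PLV) connectivity, the
    network-based statistic (NBS) with sign-flip permutation control of
    the family-wise error rate, a per-subject network index (NI) tracked
    across visits, correlation of NI changes with clinical scores, and
    motor-symptom lateralization subgroup analyses. Includes a synthetic
    longitudinal cohort generator with planted progressive connectivity
    decrements and stochastically coupled clinical scores, so the whole
    pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
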