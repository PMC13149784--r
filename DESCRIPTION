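Package: smrmosaic
Title: State-Partitioned Maintenance Metabolism and Sleep-Aware SMR Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models standard metabolic rate (SMR) as a state-dependent mosaic
    of maintenance processes partitioned across wakefulness, NREM and REM
    sleep. Provides the process-by-state partition model with state totals and
    wake-referenced multipliers, analytic curves of the per cent error in SMR
    when measurement is restricted to sleep or to wakefulness, a synthetic
    generator for bout-structured hypnograms and noisy respirometry-like rate
    traces, SMR extraction estimators (lower quantile, mean of the lowest
    normal distribution, zero-activity extrapolation), an individual-based
    simulation of overnight measurement bias in SMR and aerobic scope, a
    treatment-detectability analysis under state-restricted sampling, and the
    time-weighted integrated daily maintenance expenditure (IDME).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
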