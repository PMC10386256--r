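Package: frontier3
Title: Three-Stage Slack-Based DEA with Environmental Adjustment and
    Global Malmquist-Luenberger Productivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures panel efficiency with a slack-based measure (SBM) data
    envelopment analysis model that handles undesirable outputs and
    super-efficiency scoring on a pooled (global) frontier; removes
    environmental effects and statistical noise from first-stage input slacks
    with a normal/half-normal stochastic frontier regression and a Jondrow
    conditional-mean decomposition; re-scores the adjusted inputs; and
    computes the global Malmquist-Luenberger productivity index with its
    catch-up and best-practice (innovation) decomposition. Includes a
    synthetic panel generator with a known frontier and planted inefficiency
    for validation, delimited-file panel input/output, regional reporting
    conventions, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
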