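Package: periheading
Title: Perisaccadic Compression of Decoded and Perceived Heading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how saccadic eye movements distort the neural
    representation and perception of heading (direction of self-motion).
    Provides saccade detection from eye traces, perisaccadic alignment and
    binning of spike trains, linear heading-tuning fits with rank-based
    significance testing, an inverse-regression population decoder, a
    normalized-SD compression statistic, congruent/incongruent modulation
    indices and suppression-kernel extraction, a virtual-neuron population
    model contrasting global versus selective saccadic suppression, and the
    matching human-psychophysics analyses (behavioral compression,
    forward/backward discriminability, neural-behavioral cross-correlation,
    and reference-frame classification). Includes synthetic generators for
    optokinetic-like eye traces, linearly tuned spiking populations, and
    behavioral trial sets so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
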