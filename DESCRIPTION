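Package: tactus
Title: Agent-Based Tactus Tracking and Pulse Clarity for Symbolic Rhythms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A causal, agent-based beat-tracking model for symbolic onset
    sequences. Competing tactus hypotheses (phase/period pairs) are spawned
    from onset pairs, corrected against expressive timing by regressing a
    distance-attenuated prediction error, and scored for congruency with the
    passage (precision times sensitivity with distance-weighted hits). The
    top score over time yields a pulse-clarity curve; beat tracks are
    extracted by projecting the leading hypothesis, either naively or with
    tempo and continuity constraints. Includes deterministic synthetic
    rhythm generators (isochronous, period change, phase change, rallentando,
    mixed patterns, jittered), an inter-tap-interval variability statistic
    for tapping data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
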