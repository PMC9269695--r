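Package: wristwake
Title: Actigraphy Sleep-Wake Scoring and Polysomnography Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating wrist-accelerometer sleep estimates against
    polysomnography (PSG). Implements Cole-Kripke sliding weighted-window
    sleep-wake scoring of 60 s activity-count epochs, minute-level temporal
    alignment of paired device streams with unscorable-epoch exclusion,
    sleep-onset detection under configurable k-consecutive-minute rules, the
    standard night-level sleep measures (TST, SOL, WASO, SE and efficiency
    once asleep), epoch-by-epoch agreement statistics, Cohen's d effect sizes
    with bootstrap confidence intervals, and linear mixed-effects models of
    device and onset-rule bias with likelihood-ratio interaction testing.
    A seeded synthetic cohort generator produces paired PSG hypnograms and
    activity-count series with known ground-truth sleep architecture so the
    whole pipeline can be exercised and calibrated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
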