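Package: observeTD
Title: Temporal-Difference Model of Observing Behavior with Value-Dependent
    Disengagement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seedable simulator and fixed-point analysis of a temporal-difference
    (TD) learning account of 'observing behavior': the preference of animals for
    stimuli that reveal upcoming reward size even when the information confers no
    instrumental advantage. The model couples standard TD(0) value learning on a
    semi-Markov trial graph with a Pavlovian disengagement mechanism, a
    value-dependent per-second hazard of losing task engagement (e.g. of working
    memory for the task state), which exerts a negative bias on the learned value
    of non-discriminative cues and thereby produces an observing bias together
    with the associated pattern of reward prediction errors (the modeled phasic
    dopamine signal). Includes the observing task and its reversal, delayed-
    information and aversive variants, softmax/Luce choice with difference- and
    log-value (ratio) rules, session-level simulation with Clopper-Pearson
    confidence intervals, and a damped fixed-point solver for the self-consistent
    asymptotic values under disengagement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
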