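Package: pigtouch
Title: Touchscreen Operant Task Engine for Porcine Cognitive Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A hardware-independent engine for touchscreen operant
    cognitive tasks designed for pigs: Pavlovian autoshaping and
    multi-stage response shaping, a delay discounting task with forced-
    and free-choice trial blocks, and a color discrimination task with
    correction trials and a conditional (match-to-sample) phase. Includes
    press-on-touch hit testing with optional invisible upward hit
    extension, a two-node peripheral cue protocol (pellet dispenser,
    tone generator) with a mock transport and watchdog, per-subject
    comma-separated event logging, session summary analytics (initiation
    latency, omissions, discounting AUC, side and color preference
    indices), and simulated subject agents (hyperbolic discounting,
    softmax choice, touch scatter) so the full stack runs and is tested
    without animals or hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, yaml, jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
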