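# pigtouch

A hardware-independent engine for touchscreen operant cognitive testing in
pigs. Automated touchscreen chambers make it possible to run standardized
cognitive tasks — response shaping, delay discounting, visual
discrimination — with a pellet dispenser and tone generator driven over a
simple cue protocol. This package reimplements that task software so the
complete stack (task state machines, hit testing, peripheral control, event
logging, session analytics) runs and is tested entirely without animals or
hardware: simulated subjects with configurable choice rules and touch
topology stand in for the pigs.

It is aimed at behavioral neuroscientists building or validating operant
touchscreen protocols for large animals, and at anyone who needs a
reproducible, scriptable generator and analyzer of operant session logs.

## What is implemented

**Tasks** (all driven by a simulated clock, so sessions run in milliseconds):

- **Response shaping** — stage 0 is Pavlovian autoshaping: the whole screen
  illuminates and a pellet arrives 10 s later, but an FR-1 schedule is in
  effect throughout, so a press anywhere is reinforced immediately and
  cancels the pending delivery. Stages then shrink the reinforced region:
  full screen (stage 1), a third-of-screen rectangle at one of three heights
  (stage 2), a square of 40% screen width at one of five positions
  (stage 3), and an optional stage 4 whose square shrinks per reinforced
  trial. Advancement is automatic after 20 / 15 / 15 / 40 reinforced
  presses.
- **Delay discounting (DDT)** — a Large button paying 4 pellets versus a
  Small button paying 1. Delays to the Large reward increase across
  within-session blocks (default 0, 5, 10, 20 s, one block per 12 trials);
  each block gives 6 forced-choice then 6 free-choice trials. Button
  reversal is a one-call config transform.
- **Color discrimination** — centre sample box, then two choice boxes with
  pseudorandomly balanced sides. Three phases: simple (yellow reinforced,
  blue comparison), correction (an incorrect choice immediately re-presents
  the identical trial with the incorrect box visible but inactive), and
  conditional match-to-sample (a green or blue sample; only choices of that
  color reinforced), optionally under FR-3 on sample and choice buttons.

**Infrastructure**: press-on-touch hit testing (releases never register, an
invisible hit region can extend above each button to absorb upward swipes),
a two-node peripheral cue protocol (cue `"1"` cycles the pellet dispenser,
`"2"` turns the tone on for 1 s; unknown cues are logged as stray signals,
and an optional watchdog forces outputs off after a timeout), 2900 Hz
response-feedback and 7500 Hz trial-start audio cues, and per-subject CSV
event logs from which every metric is recomputable.

**Analytics**: per-session trial reconstruction and summary — trials
completed, omissions, mean initiation latency, percent correct (correction
trials excluded from the denominator), discounting AUC, and side/color
preference indices on a −1..1 scale. The discounting AUC is, by default,
the proportion of completed free-choice trials on which Large was chosen
(bounded in [0, 1]); the conventional trapezoidal delay-normalized AUC

AUC = Σᵦ (dᵦ₊₁ − dᵦ)(pᵦ + pᵦ₊₁) / 2,  d normalized to the maximum delay,

is available as `mode = "trapezoid"`. Simulated subjects value delayed
rewards by the standard hyperbolic (Mazur) discount, V = A / (1 + kD),
optionally softened by a softmax, with side/color bias terms and a
press-and-swipe-upward touch model.

## Worked example

A subject discounting at k = 0.5 per second runs a default DDT session.
With magnitudes 4 vs 1, hyperbolic value predicts Large preference while
D < 3/k = 6 s — so Large at the 0 and 5 s blocks, Small at 10 and 20 s:

```r
library(pigtouch)
agent <- agent_policy("hyperbolic", k = 0.5, response_latency_mean = 3)
s <- simulate_session("ddt", agent, subject_id = "pig1", seed = 42,
                      quiet = FALSE)
#  subject_id session_id task trials_total trials_completed omissions
#        pig1          1  ddt           48               48         0
#  mean_initiation_latency reinforcers_delivered percent_correct auc side_bias
#                 3.979458                   120              NA 0.5         0
#  color_bias
#          NA
```

48 trials (4 blocks × 12) completed with no omissions; 120 pellets
(Large and forced trials included); AUC 0.5 because exactly half the 24
free choices were Large. Per-block Large-choice proportions confirm the
predicted switch point:

```r
log <- attr(s, "log")
tr  <- session_trials(log)
free <- tr[tr$trial_type == "free_choice" & !tr$omitted, ]
aggregate(list(p_large = free$choice == "large"), list(delay = free$delay), mean)
#   delay p_large
# 1     0       1
# 2     5       1
# 3    10       0
# 4    20       0
discounting_auc(tr, "trapezoid")
# [1] 0.375
```

The same stack is scriptable from a shell:

```sh
Rscript inst/scripts/pigtouch.R simulate --task ddt --agent hyperbolic \
    --k 0.5 --seed 42 --subject pig1 --out-dir out
Rscript inst/scripts/pigtouch.R summarize out/pig1_s1.csv
```

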