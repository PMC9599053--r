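---
title: "The pigtouch task engine: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pigtouch task engine: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigtouch)
```

pigtouch is a task engine for touchscreen operant testing in pigs, built so
the entire behavioral stack runs headlessly: every task is a deterministic
state machine over a simulated clock, every stochastic draw flows from one
session seed, and every outcome metric is recomputable from the session's
CSV log. This vignette documents the science and the engineering choices a
maintainer or user should know about.

## The tasks and their assumptions

### Response shaping

Shaping proceeds through stages that progressively restrict where a press
is reinforced. Stage 0 is Pavlovian autoshaping with a concurrent FR-1:
the screen illuminates yellow, a pellet arrives noncontingently 10 s later,
but any press in the meantime is reinforced at once. The engine resolves
the overlap of the two schedules by cancellation: a reinforced press
cancels the pending noncontingent delivery, so exactly one pellet is
delivered per illumination. This is the only reading under which the FR-1
is meaningful (a press would otherwise just add a second pellet) and it
makes pellet accounting exact. Noncontingent deliveries do not count
toward stage advancement; reinforced presses do.

Stages 1–3 reinforce presses on a full screen, a full-width rectangle one
third of the screen high at one of three heights, and a square of side 40%
of screen width at one of five positions (offset from each corner by 0.05
screen fraction, and centred). Position draws are uniform and independent;
we deliberately do not exclude immediate repeats, because repeat exclusion
would bias the empirical position frequencies away from uniform and the
tracking demand it adds is not part of the staged contingency. Advancement
thresholds are 20, 15, 15 and 40 reinforced presses; after the stage-3
threshold the subject is flagged ready for testing. The optional stage 4
shrinks the square by a configurable decrement (default 0.02 screen
fraction, floor 0.1) per reinforced trial, for protocols that need finer
response precision.

The geometry is expressed entirely in screen fractions (origin top-left),
so layouts are resolution independent; a display backend maps the color
tokens to RGB (yellow `#FFFF00`, blue `#0000FF`, green `#00FF00`).

### Delay discounting

Two buttons pay 4 ("Large") and 1 ("Small") pellets. A session is a
sequence of blocks, one per delay, delays strictly ascending (default 0,
5, 10, 20 s; alternative sets such as 0, 1, 2, 4 s are plain config
changes). Each 12-trial block opens with 6 forced-choice trials — 3
Large-only and 3 Small-only, order shuffled — followed by 6 free-choice
trials. Forced trials precede free trials because their function is to
expose the subject to the block's new delay before choice is measured;
with nothing said either way in standard protocols, interleaving would let
early free choices be made before the subject has sampled the delayed
outcome. The delay applies to the Large reward only; Small always pays
immediately. A magnitude discrimination is simply `delays = c(0)`, and
moving a subject from magnitude discrimination to delays is an
experimenter decision made in the config (protocols use a judgment
criterion — stable Large preference — rather than an algorithmic one, so
the engine does not auto-advance). `reverse_buttons()` flips which side
Large occupies and is an involution.

Pellet commands for a multi-pellet reward are issued back-to-back by
default (`pellet_cycle_time = 0`): the cue channel is instantaneous even
though the physical dispenser cycles take time, and spacing is a config
knob for deployments that need it.

### Color discrimination

Each trial presents a centre sample box; fulfilling its fixed-ratio
requirement brings up the two choice boxes. In the simple and correction
phases the sample and the correct choice are yellow with a blue
comparison; in the conditional phase the sample is green or blue (drawn
per trial) and only choices matching it are reinforced — yellow does not
appear in the conditional phase, since the conditional contingency is
defined entirely over the green/blue pair. After an incorrect choice in
the correction and conditional phases, the next trial re-presents the
identical layout (same sides, same colors) with the incorrect box rendered
but inactive; a correction pending when the session's scored-trial quota
is reached still runs before the session ends, so every incorrect choice
has its correction.

Correct-choice sides are pseudorandom: balanced within blocks of 6 (three
left, three right) with runs of the same side capped at 3, by rejection
sampling. Pure randomization produces long side runs that interact badly
with pigs' documented side biases; strict alternation is learnable. The
block-balanced, run-capped scheme is the standard compromise.

Accuracy excludes correction trials from its denominator. A correction
trial's only selectable option is the correct one, so including
corrections would mechanically inflate percent correct; this is the
standard convention for correction procedures, and correction trials
remain in the log and in trial counts.

## Hit testing and the touch topology

Responses register on the initial press; releases never register. Pigs
press and then swipe upward at a slight diagonal, so release-based
registration (the default of common GUI toolkits) both misses and
mislocates responses. For the same reason each response box can carry an
invisible hit region extending above its visible rectangle
(`hit_extension_above`, a screen fraction); the default is 0 — off —
because it is a proposed mitigation rather than part of the base
procedure, and tasks enable it explicitly. Layouts are validated at
construction: all boxes inside the unit square, and no two *active*
touchable regions (visible rectangle plus extension) may overlap, so a
press can never be ambiguous. Inactive boxes (the disabled option of a
correction trial, the unavailable button of a forced trial) are rendered
but never register. No touch debouncing is applied: every press is an
event, and rapid repeated presses are exactly what fixed-ratio counters
must count.

## The peripheral protocol

Peripherals sit behind a cue table mapping received tokens to actions
(defaults: `"1"` → one pellet-dispenser cycle, `"2"` → tone on for 1 s).
The radio link is modelled as an ordered lossless channel; unknown tokens
— stray radio pickup is a real failure mode — change no output and are
logged as stray-signal notes. A second tone cue while the tone is on
extends the off time to one duration after the later cue (extension rather
than ignore-while-on: the receiving node is stateless and simply restarts
its timer). The optional watchdog (`watchdog_timeout`, seconds; disabled
by default) forces any output off once that long has passed without a
received cue, bounding the damage of a corrupted "on": with timeout T, no
output ever stays on more than T past the last cue.

Audio cues are fixed by the deployed hardware: 2900 Hz on every
registered response (press feedback) and 7500 Hz at trial start (button
availability), each logged as a tone event.

## Simulated subjects

An agent is a choice rule plus a response topology:

- **Choice.** Options are scored by hyperbolic discounted value
  V = A/(1 + kD) (k per second, default 0) plus bias offsets: side and
  color biases in [−1, 1] scaled by half the option magnitude range, so a
  full bias is worth half the Large–Small gap. Greedy agents
  (`temperature = 0`) take the argmax with seeded tie-breaks; positive
  temperature applies a softmax over the scores. `perfect` and
  `hyperbolic` agents are contingency-aware (in the discrimination task
  the correct option carries value 1, the incorrect 0); `biased` agents
  are contingency-naive — the reward structure does not enter their
  scores, only biases and noise — which is what makes them produce errors
  and the −1..1 preference indices at their extremes. `random_toucher`
  picks uniformly among active options; `nonresponder` never touches.
  Omissions are a per-trial Bernoulli draw (`omission_prob`).
- **Topology.** A press lands at the target centre plus Gaussian scatter
  (`touch_sd`) displaced upward by `swipe_offset` (screen fractions), with
  the release displaced further upward — the press-then-swipe-up pattern.
  With `swipe_offset` equal to a box's `hit_extension_above`, registration
  recovers, which is the property the extension exists for.
- **Latency.** Response latencies are exponential with mean
  `response_latency_mean` (seconds): memoryless, strictly positive,
  right-skewed like real initiation latencies, and controlled by one
  parameter. A 0.05 s floor keeps event timestamps strictly ordered at
  millisecond log precision.

The agents emulate choice allocation, response topology, omissions and
latencies. They do not emulate learning (acquisition curves), motivation
drift within a session, or competing behaviors like rooting; a passing
test therefore validates the *engine's* contingencies and accounting, not
any claim about how quickly real pigs acquire these tasks.

## Logging and analysis

Every event is one CSV row with fixed columns (`subject_id, session_id,
task, phase, trial_index, event_type, timestamp_s, x, y, payload`), one
file per subject, header always written, absent values as empty fields,
payload RFC-4180 quoted. The schema is this package's own (the field
convention is only that sessions are per-subject CSVs). Timestamps are
seconds from session start at millisecond precision; coordinates are
screen fractions rounded to 1e-6. Both roundings happen at record
creation, which is what makes the write/read round trip an identity. The
session seed is recorded in a header event, so a log is a complete,
reproducible record; all metrics (`summarize_session()`) are computed
from the log alone.

The discounting AUC defaults to the *proportion of completed free-choice
trials on which Large was chosen*, pooled across blocks — 1 means every
free choice was Large, 0 none. The conventional trapezoidal
delay-normalized AUC over per-block proportions is provided as
`mode = "trapezoid"` and labelled distinctly, because the two disagree
whenever choice varies across blocks (the pooled proportion weights
blocks by completed trials; the trapezoid weights by delay spacing).
Pooling is the default because it is well-defined even for a single-block
session and is robust to unequal completed-trial counts; with equal
counts per block it equals the mean of per-block proportions. Omitted
trials are excluded from every denominator. Preference indices are
(L − R)/(L + R) and (G − B)/(G + B) over completed free choices, positive
toward left and green.

## Numerical and degenerate-input conventions

- Omission window: 60 s per trial, configurable; intertrial interval 15 s
  fixed (protocol guidance keeps ITIs under 20 s, which the config
  enforces).
- Zero completed free choices, zero scored discrimination trials, or zero
  initiated trials make the corresponding metric `NA` rather than 0 — an
  absent estimate, not an extreme one.
- Out-of-order timestamps are rejected at logging time, per
  subject/session; malformed CSV lines are reported with their line
  number.
- Ties in greedy choice are broken by a seeded draw, so sessions are
  byte-reproducible for a given seed and config.

## Problem sizes in the test suite

The suite verifies uniformity of stage-2 positions with 3000 draws
(chi-square), correction-trial layout identity over 250-scored-trial
sessions (≈370 trials with a noisy agent), pellet conservation over 1000
random cues, CSV round-trip identity over 100 randomized logs, and the
k-ordering of the discounting AUC over four full DDT sessions — sizes
chosen to give the statistical checks power while keeping any single test
file in the low seconds on the simulated clock.

## Known limitations

- No learning dynamics in the agents; acquisition-rate phenomena cannot be
  simulated.
- The real-hardware transport (radio link, GPIO, audio synthesis) is a
  plug-in point; only the mock transport ships.
- Statistical inference across subjects or sessions is out of scope; the
  package reports per-session descriptive metrics.
- The experimenter-delivered interventions that occur in practice (e.g.
  differential reinforcement of other behavior with treats, motivating a
  reluctant subject) are representable only as `manual_note` events.
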