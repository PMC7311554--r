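---
title: "Modelling generosity, attention, and effort in intergroup allocation decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling generosity, attention, and effort in intergroup allocation decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intergaze)
```

## The scientific problem

People are systematically more generous toward members of their own group
than toward outgroup members, and people with stronger prosocial
preferences show this ingroup bias more strongly. `intergaze` packages a
complete modelling-and-measurement pipeline for studying the cognitive
side of this phenomenon in decomposed (minimal) dictator games with
eye-tracking: a decision maker repeatedly chooses between two allocations
of money between themselves and a passive partner who is either an
ingroup or an outgroup member, while gaze is recorded.

The pipeline has five connected layers:

1. a **discounted social-utility model** of the choice,
2. **Social Value Orientation (SVO) slider scoring** to measure prosocial
   preference,
3. a **gaze-processing stage** (fixation detection, AOI metrics,
   exclusion rules),
4. a **gaze-contingent sequential-sampling simulator** (attentional
   drift-diffusion) that turns utilities into choices, response times,
   and fixation sequences, and
5. an **analysis stage** (mixed-effects models of generosity, attention,
   and effort, plus a Monte Carlo power procedure).

A synthetic-experiment generator with known ground truth ties the layers
together, so the whole pipeline is testable end to end without any
external data.

## The utility model

An allocation option pays `own` to the decision maker and `other` to the
partner. Utility weights the two payoffs,

$$U = w_{own}\,u(\text{own}) + \beta\, w_{other}\,u(\text{other}),$$

with $u$ the identity transform, and $\beta = 1$ for ingroup partners
and $0 < \beta < 1$ for outgroup partners: the partner's payoff is
multiplicatively discounted when they belong to the outgroup. Two
archetypes recur throughout the package: a *prosocial* decision maker
with $w = (0.5, 0.5)$ and an *individualist* with $w = (0.9, 0.1)$.

```{r}
A <- allocation_option(7.50, 5.20)
B <- allocation_option(6.90, 6.10)
prosocial <- social_preference(0.5, 0.5)
outg <- group_context("outgroup", beta = 0.5)
c(in_A = utility(A, prosocial), in_B = utility(B, prosocial),
  out_A = utility(A, prosocial, outg), out_B = utility(B, prosocial, outg))
```

The prosocial archetype prefers B with an ingroup partner but flips to A
under outgroup discounting, while the size of the utility difference —
which drives decision effort below — changes far more for prosocials
(`context_shift(A, B, prosocial, 0.5)` = 0.075) than for individualists
(0.045).

Two declared conventions: weights are not normalized (the archetypes
above do not sum their squares to one and need not), and choices within
`1e-9` utility of each other count as ties, resolved by a seeded random
draw by default. $\beta$ is a free simulation parameter; nothing in the
model pins it empirically, and the default 0.5 follows the archetypal
example. Utility is linear in each payoff; `utility` refuses $\beta$
outside $(0, 1]$.

A caveat worth stating: the absolute change in $|U_A - U_B|$ between
contexts (`context_shift`) is *not* globally monotone in $\beta$. When
the signed difference changes sign between contexts — exactly the
prosocial flip above — $|U_A - U_B|$ is V-shaped in $\beta$ and the
shift peaks at the crossing. It is monotone whenever the preference
ranking survives discounting, and the closed form
$(1-\beta)\,w_{other}\,|other_A - other_B|$ applies only in that regime.

## SVO scoring

Prosocial preference is measured with the six primary items of the SVO
slider measure: each item offers nine (self, other) allocations; the
chosen allocations are averaged and the angle
$\arctan\big((\bar{a}_{other} - 50)/(\bar{a}_{self} - 50)\big)$
summarizes the trade-off, with 0° pure self-interest and 45° equal
weighting. Classification uses the conventional open intervals
(prosocial 22.45°–57.15°, individualist −12.04°–22.45°), with exact
boundary values labelled rather than silently assigned. When the mean
self-allocation equals the neutral point 50 the slope is undefined; the
angle is reported as 90° only when the mean other-allocation exceeds 50,
otherwise scoring fails loudly.

Two open conventions were settled as follows: means are taken across
items before centering at 50 (the standard convention for the measure),
and the bridge from angle to model weights is $w_{own} = \cos\theta$,
$w_{other} = \sin\theta$, which preserves the angular geometry exactly
(`atan(w_other/w_own)` recovers the angle); the alternative
$w_{own} = 1 - w_{other}$ compresses extreme angles and is documented
but not implemented.

## Gaze processing

**Fixation detection** uses the dispersion-threshold (I-DT) rule:
greedy left-to-right maximal windows whose summed x-range plus y-range
stays within 30 px, emitted as fixations when they last at least 50 ms.
A window's duration counts each sample as one frame
(`t_last - t_first +` the nominal frame period), so at 120 Hz six
samples span exactly 50 ms and the comparison is inclusive. Because
dispersion can only grow as a window extends, the greedy window is the
maximal admissible window at its start; the test suite checks
equivalence against a brute-force oracle that recomputes every window's
dispersion from scratch. Binocular recordings are averaged per
timestamp before detection, falling back to the valid eye when one eye
drops out.

**AOIs** are half-open rectangles `[x0, x0+w) × [y0, y0+h)` (origin
top-left, 0-based pixels), so a centroid on a shared edge belongs to
exactly one AOI; overlapping layouts are rejected. The emulated screen
holds 15 AOIs: eight 100×100 payoff cells (own, other, difference, sum
for each option), four 100×190 row labels, and three 100×100 identity
items — the partner's group membership plus two undiagnostic controls
(a coin toss and a personal code).

**Trial metrics** include the effort measures (response time, fixation
count, distinct AOIs inspected with all 15 on-screen AOIs as the
proportion denominator) and attention shares. `attention_own` uses only
own- vs other-payoff cells in its denominator, since the construct is
the trade-off between own and others' outcomes; a variant over all
eight payoff cells is emitted alongside for sensitivity checks.

**Exclusions** run in a declared order: flagged participants out first
(wrong outgroup named, outgroup identification or liking at least
ingroup-level, demand-check failure, missing gaze); then trials with
under 50% of fixations on payoff-plus-identity AOIs; then the
response-time cut (under 200 ms, or above the pooled mean plus 3 SD
*computed on the survivors of the previous rule* — the order changes
the threshold, so it is fixed and reported). The pooled (not
per-participant) mean follows from treating the decision-time
distribution as one dataset, and filler trials are ordinary trials for
this purpose. For process analyses only, trials in which the
group-membership AOI received no gaze sample at all (fixation or not)
are additionally dropped. The filter is idempotent once the
response-time statistics are frozen, and it reports counts per rule.

## The attentional drift-diffusion simulator

Evidence (the Relative Decision Value) accumulates in 1 ms
Euler–Maruyama steps with drift
$d\,(U_{att} - \theta\, U_{unatt})$ signed toward the currently fixated
option, noise $\sigma\sqrt{dt}$, and absorption at $\pm a$; fixations
alternate between options with log-normal durations, and response time
adds a non-decision constant. Larger utility differences mean steeper
drift, hence faster decisions with fewer fixations — the mechanism that
links the discounting model to effort predictions.

All quantitative parameters are simulator configuration, with defaults
chosen once and documented: $d = 0.0025$ per ms per utility unit,
$\sigma = 0.02$ per $\sqrt{ms}$, $a = 1$, $\theta = 0.95$, non-decision
time 300 ms, fixation durations log-normal with median 300 ms. Utilities
enter on the raw EUR scale (around 5–7), so an aggressive attentional
discount would let the *common* utility level dwarf the decision-relevant
difference; $\theta = 0.95$ keeps the gaze advantage mild, and
$\sigma = 0.02$ puts mean decision times in the 1–2.5 s range while
leaving them sensitive to utility differences between roughly 0.05 and
0.7 — the range the allocation trials produce. In the $\theta = 1$,
single-fixation limit the simulator is a plain drift-diffusion process
and its choice probabilities are checked against the closed form
$P = 1/(1 + e^{-2 a d \Delta U / \sigma^2})$; whether the effort
predictions require $\theta < 1$ is left open by design, and both
regimes are exposed.

`simulate_cohort` adds the fixation micro-structure the diffusion
process does not specify: each option fixation lands on a concrete
payoff cell (biased 40/25/20/15 toward the own-payoff row), and trials
open with two to four identity-box fixations biased 3:1:1 toward the
diagnostic group-membership item, with a 5% chance of skipping the
identity box entirely (those trials later fall to the process-analysis
exclusion). Its output uses the same schema as the gaze-pipeline
metrics, so the analysis stage cannot tell simulated from recorded data.

## The synthetic experiment

The generator emulates the study design: two within-subject group
contexts with 28 target and 12 filler trials each, a 1280×1024 screen
sampled at 120 Hz, counterbalanced block positions (identity box and
payoff block each at top/middle/bottom, nine cells), own payoffs on
2.40–10 EUR targeting mean 7.18 and SD 2.04, receiver payoffs on
0.10–7.80 EUR targeting mean 3.03 and SD 2.22.

Choices that were genuinely open, settled as follows:

* **Payoff law.** Payoffs follow a range-scaled Beta whose shapes are
  solved in closed form from the target mean and SD. The printed
  own-payoff moments sit at the edge of what a truncated normal can
  express on this range (moment matching degenerates toward an
  exponential-tilt limit with unstable sampling), while the bounded Beta
  family covers them exactly.
* **Within-trial structure.** A trial is a midpoint plus a contrast: own
  payoffs are `m ± cost/2` with the prosocial cost uniform on 0.30–0.90
  EUR, receiver payoffs `mo ∓ benefit/2` with the benefit uniform on
  0.60–1.20 EUR — centered on the archetypal worked options (cost 0.60,
  benefit 0.90). This keeps the dictator's payoff above the receiver's
  in both options, makes the prosocial choice always costly and always
  beneficial, guarantees the option sums differ (their difference,
  benefit − cost, is the efficiency control), and gives pooled payoffs
  the target moments (midpoint variance is reduced by the contrast's
  share, with a small fixed-point correction for per-trial range
  clipping). The percentage-of-disadvantage control lands near the
  archetypal 8%.
* **SVO distribution.** Angles mix two normal modes at the archetypes —
  45° (SD 5) with weight 0.6 and 6.3° (SD 5, the 0.9/0.1 decision
  maker) with weight 0.4 — resampled into (−16°, 61°). Under this
  population and β = 0.5 the generative model produces the qualitative
  pattern the utility model implies: a positive ingroup effect on
  generosity, a positive SVO×group choice interaction, and a negative
  SVO×group interaction on log effort.
* **Fillers** follow the same payoff law and are flagged; their exact
  structure is not specified anywhere, and treating them as ordinary
  trials is the least surprising choice.
* **Gaze synthesis.** `generate_gaze` inverts the preprocessing stage:
  AOI-centre fixations with Gaussian jitter truncated to ±7 px per axis
  — so a planted fixation's dispersion can never breach the 30 px
  tolerance — joined by two interpolated saccade samples, which are too
  brief to form spurious fixations. Round-trip recovery of the planted
  count, AOI sequence, and centroids is exercised across seeds and
  jitter levels up to 5 px.

What the generator does *not* emulate: smooth pursuit, blinks and
tracking dropouts, calibration drift, head movement, anticipatory or
expressive fixations, learning or fatigue beyond a trial-index term, and
any dependence of gaze on payoff magnitudes within an option. Passing
tests therefore certify the pipeline's internal consistency — detection,
metrics, exclusions, model recovery — not robustness to every artifact
of real recordings.

## Analysis stage

`fit_models` mirrors the three model families: a mixed-effects logistic
regression of prosocial choice on centered SVO angle, group setting, and
their interaction (controlling percentage of disadvantage and
efficiency), and linear mixed models for attention to own outcomes and
the three effort measures (log response time in seconds, log fixation
count, proportion inspected) with a trial-index control. Random effects
are a participant intercept — the repeated-measures structure named by
the design — with a random group slope available behind a flag.
Centering happens inside the fitting function, so shifting a predictor
by a constant cannot change any reported effect. Model fitting itself
is delegated to `lme4`; the package's own content is the generative
model, the regressors, the pipeline, and the power procedure.
Non-convergence is flagged on the result, never raised. No
multiple-testing correction is applied, matching the analysis
convention of the design (two-sided 0.05).

`power_simulation` implements power-by-simulation for the choice model:
a sampling frame (fixed effects on the log-odds scale, random-intercept
SD, SVO spread, trial counts) generates data at each candidate sample
size, the mixed logistic model is refit, and Wald rejections are
counted over 500 replications, run under at least two seeds so the
stability of the estimates is visible. Refits use `nAGQ = 0`, which is
accurate enough for rejection rates and an order of magnitude faster.
With a frame holding strong main effects and a weak interaction, main
effects reach 80% power at a fraction of the interaction's requirement
— the qualitative situation that motivates simulation-based power
planning for interaction hypotheses.

## Problem sizes and numerical choices

The test suite runs the oracle-equivalence property on 1,000 random
inputs of up to 50 samples, the gaze round trip on 500 planted trials,
parameter recovery on 50 replications of an 80-participant cohort, the
closed-form diffusion check at 10,000 simulated trials, and the power
calibration at 500 replications — sizes at which every Monte Carlo
tolerance used is conservative. Dispersion and duration comparisons use
a `1e-9` slack so exact boundary cases are stable; tie-breaking in
choice prediction is explicit; degenerate inputs (empty gaze streams,
zero payoff dwell, undefined slider slopes, non-absorbing diffusion
paths) are flagged or rejected rather than silently propagated.

## Known limitations

The aDDM is used as a generator, not fitted to data (no likelihood
estimation); multi-alternative races, inequity-aversion or reciprocity
utilities, and velocity-based (I-VT) fixation detection are out of
scope. The power stage covers the logistic choice model only. Reported
effect magnitudes from simulated cohorts are simulator-dependent by
construction; only their directions carry meaning.
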