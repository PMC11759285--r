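---
title: "Serial fixed-interval timing: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial fixed-interval timing: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfiadapt)
```

This vignette is the package's account of its science: the task and agent
model behind the simulator, the exact definitions of the four start-time
estimators, the change-point model and its calibration, the transition
analyses, and the design choices made where more than one reasonable
definition existed.

## The task

A serial fixed-interval (sFI) session presents fixed-interval trials in
blocks. Within a trial the subject may press freely; the first press at or
after the FI deadline delivers the reward and starts the next trial —
nothing else marks trial or block boundaries. FI durations
(12, 24, 36, 48, 60 s by default) and block lengths (13, 15, 17, 19, 21
trials) are drawn without replacement from their lists; an exhausted list
refreshes, and both lists start fresh every session. Sessions end at 100
rewards or 90 minutes, whichever comes first. Because every trial ends in a
reward and pressing commonly brackets the reward, all start-time analysis
ignores the first 5 s of each trial, and sessions are analysed only through
their first five blocks, where engagement is reliable.

Variants: a *novel-interval* protocol replaces the trained durations with
13, 15, 31, 45, 57 s (each within 60–140% of the trained value it
replaces — `validate_duration_ratios()` checks this property for any
candidate list); a *de novo* protocol rescales each base duration by an
independent uniform factor in [0.8, 1.2] every session, so no exact
duration repeats across days.

## The simulated presser

No public data accompany this task, so the package ships a generative agent
whose sessions reproduce the statistical structure the analyses rely on.
The agent is a reduced scalar-timing presser, summarising
threshold-crossing accumulator models in two numbers:

* it presses at a baseline rate $\lambda_0$ from the end of a post-reward
  consumption pause, and at $\lambda_0 + \lambda_1$ from a trial-specific
  start time onward (both homogeneous Poisson processes);
* the start time is drawn from
  $\mathcal{N}(k\,\hat{s},\ (w\,k\,\hat{s})^2)$ truncated below at the
  consumption pause, where $\hat{s}$ is its current estimate of the FI.
  $k = 0.5$ matches the observed blockwise scaling of rodent start times
  (slope ≈ 0.5 of the interval, a response threshold at about half the
  accumulator's maximum); $w$ is a Weber fraction, giving the scalar
  property (timing noise proportional to the timed duration);
* after every reward the estimate moves toward the experienced trial
  duration by a delta rule, $\hat{s} \leftarrow \hat{s} + \alpha\,(T -
  \hat{s})$. The experienced duration $T$ is the trial's reward time — the
  only duration feedback the task delivers. $\alpha = 1$ is one-shot
  updating (the `"fast"` preset); $\alpha = 0.2$ (`"slow"`) and smaller
  values give gradual updating for contrast experiments.

An emergent and realistic asymmetry: after an interval *increase* the
agent's first reward under the new FI arrives at ≈ the new FI, so a
one-shot learner is fully adapted on trial 2; after a *decrease* the reward
arrives whenever the still-late pressing happens to occur, so even the
one-shot learner converges geometrically over a few trials. Decreases are
genuinely harder to learn from, as observed in animals.

### Default parameters

| parameter | default | units | why |
|---|---|---|---|
| `baseline_rate` | 0.1 | presses/s | sparse "lever-sampling" (~6/min); keeps a change point detectable on most trials |
| `high_rate` | 2 | presses/s | burst-like engaged FI pressing; IPIs ~0.5 s |
| `threshold_fraction` | 0.5 | — | observed start-time/FI slope ≈ 0.5 |
| `weber_cv` | 0.2 | — | rodent-range timing variability |
| `learning_rate` | 1 (fast) / 0.2 (slow) | — | one-shot vs gradual presets |
| `consumption_delay` | 1 | s | eating pause; set to ~8 s to emulate mice whose pause swallows most of a 12 s trial |
| `initial_estimate` | 36 | s | mid-range of the duration list |

The high-state rate matters more than it looks: the burst estimator waits
for two fast inter-press intervals after the true start, and that wait is
censored by the trial's end. At ~1 press/s the wait is ~5 s and the
censoring differs systematically between short and long trials, inflating
the burst estimator's blockwise slope; at 2 presses/s the wait is ~1–2 s
and the slope recovers the programmed 0.5. The defaults were fixed, once,
with this geometry in mind.

What the generator does **not** emulate: pressing that continues past the
reward (trials end at reward here, which truncates trial-1 values after
decreases — see below), within-session satiety drift, slow acquisition
(sessions are generated at steady state), and any richer accumulator
dynamics than the two-state start-time summary. Passing tests therefore
validate the estimators and analyses against a known ground truth, not
against every feature of animal data.

## The four start-time estimators

All estimators are censored at `min_start_time` (5 s) and computed
independently per trial; a trial on which an estimator is undefined is
`NA`, and missing values are excluded pairwise downstream, never imputed.

* **First press** — the earliest press ≥ 5 s.
* **First burst** — the first run of three presses whose two IPIs both fall
  at or below the experiment-wide fast-IPI threshold: the nearest-rank
  (type-1) 40% quantile of all within-trial IPIs pooled across every
  subject and session of the experiment. Pooling at the experiment level
  normalises for cohort-wide differences in pressing vigour. The burst's
  timestamp is its first press (its visible onset); the earliest burst
  whose first press clears 5 s wins. Nearest-rank quantiles and the
  inclusive comparison (IPI ≤ threshold) make the definition reproducible
  without interpolation ambiguity.
* **Press-rate increase** — presses are counted in 1 s bins, smoothed by a
  centred 3-bin moving average truncated at the edges (no phase lag), and
  the estimator returns the left edge of the earliest bin, starting at or
  after 5 s, whose smoothed rate is strictly greater than 2× the
  session-average press rate (total presses over total trial time, whole
  session).
* **Change point** — below.

## The change-point detector

The trial's IPI sequence is modelled as exponential waiting times with a
possible one-time rate change. With a conjugate Gamma(a, b) prior on each
rate, the marginal likelihood of a segment is closed-form,
$$m(x_{1:n}) = \frac{\Gamma(a+n)}{\Gamma(a)}\,
  \frac{b^a}{(b+\sum x_i)^{a+n}},$$
and the evidence for a change at split $c$ against no change is the Bayes
factor $\exp[m(x_{1:c}) + m(x_{c+1:n}) - m(x_{1:n})]$ (log scale inside).
The detector processes IPIs online: after each new IPI it takes the
**maximum** Bayes factor over admissible splits of the data so far (ties to
the earliest split), and the first time this reaches 10 it reports the
press that terminates the IPI at the best split — the press beginning the
new-rate regime — provided that press falls at or after 5 s; otherwise
scanning continues. Only the first change point per trial is kept.

Maximising over splits *and* stopping at the first qualifying prefix is a
double maximisation, so the nominal "Bayes factor 10" bar is far more
permissive than it sounds: with an uncalibrated unit-scale prior the
false-detection rate on exchangeable (no-change) 30-IPI sequences is ~27%.
The packaged default prior is therefore deliberately diffuse and
scale-anchored — $a = 0.25$, $b = 4 \times$ the median pooled IPI of the
experiment, fixed before any per-trial analysis — which calibrates the
false-positive rate to ≲ 4% at threshold 10 while keeping ≥ 85% detection
with sub-second median timing error for the ~8× rate steps a response
start produces. Bayes factors are invariant to rescaling time when $b$
rescales with it, so the calibration carries across species and pressing
vigour. `cprl_config()` exposes all of `a`, `b`, the threshold and the
minimum segment length (default 1 IPI per side).

## Transition analyses

For each boundary between consecutive analysed blocks, the previous block's
mean of an estimator (pairwise deletion) is the record's baseline; the
estimator's values on the first `t_post = 10` trials of the new block are
expressed as a percentage of it, computed as `100 * (value / baseline)` so
a value equal to its own baseline is exactly 100. Ten post-transition
trials cover the shortest block length (13) with headroom and match the
granularity at which adaptation saturates.

* **Direction** follows the sign of the FI change; *trial 1* is the first
  trial experienced under the new FI, so nothing can differ on trial 1 by
  construction (except the truncation artifact after decreases noted
  above).
* **Magnitude** uses the rank gap $g$ in the session's ordered duration
  list: $g = 1$ adjacent → *small*; $g \ge 3$ (two or more durations
  strictly between) → *large*; $g = 2$ is reported as an explicit
  *intermediate* class rather than silently folded into either, since the
  two standard definitions do not cover it.
* **Shortest-duration exclusion**: for the burst, rate-increase and
  change-point estimators, transitions to or from the session's shortest
  duration are dropped — pressing there is too sparse for those estimators
  (mice especially, where the consumption pause swallows most of a 12 s
  trial). The first press keeps all transitions. The exclusion keys on the
  *rank* of the duration within the session's own list, not the literal
  value 12, so it applies unchanged to novel-interval and rescaled
  sessions.
* **Adaptation latency** replaces repeated-measures ANOVA machinery with a
  transparent equivalent: at each post-transition trial, a two-sided
  one-sample t-test of the record-level normalised values against 100%,
  Holm-corrected across the ten trials; the latency is the first trial with
  adjusted p < 0.05. The record-level table is exported so any external
  stats package can run richer models.
* **Correlation build-up**: at a fixed trial-within-block index, (FI,
  estimate) pairs are pooled across blocks 2–5 (block 1 has no preceding
  transition) and subjects, and summarised by Pearson's r with the t-based
  two-sided p. Fewer than 3 complete pairs, or zero variance on either
  axis, yields a missing result.

## Numerical and I/O conventions

All event times are carried at 1 ms resolution: simulated press times are
snapped to the exact double their three-decimal text form parses back to,
so event logs round-trip through CSV bit-for-bit, and the reward rule
("first press ≥ FI") is evaluated on that grid. Two presses are never
closer than 1 ms. Degenerate inputs are defined rather than erratic: empty
trials give all-`NA` estimates; an all-identical IPI pool makes the
fast-IPI threshold that constant; a zero-variance test sample yields a
missing latency test; ties in the change-point argmax break to the earliest
split. Every stochastic function draws from R's RNG, sessions record their
seed, and per-session seeds in `simulate_cohort()` derive from one master
seed, making whole cohorts exactly reproducible.

Problem sizes used by the shipped tests and the acceptance script — e.g.
cohorts of 10–20 subjects × 1 session, 500-replicate calibration runs,
10,000-sequence oracle sweeps, 1,000-session invariant sweeps — were chosen
as the smallest sizes at which the Monte-Carlo error of each checked
quantity is comfortably inside its assertion margin.

## Known limitations

* Trials end at the reward, so post-decrease trial-1 values are truncated
  downward; real pressing extends past the reward and real trial-1
  baselines are flatter.
* The agent's learning is a scalar delta rule; it cannot express memory of
  previously trained duration lists, and the de novo protocol exists
  precisely to keep such memorisation out of the analyses.
* The detector models IPIs as exponential within states; strongly
  patterned pressing (e.g. rhythmic bouts) would violate that and shift
  the calibration.
* Session-level statistics (ANOVA across subjects and species, post hoc
  families) are out of scope by design; the tidy tables are the interface
  to external statistical tooling.
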