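# sfiadapt

Analysis tools for **serial fixed-interval (sFI)** operant behaviour: a task
in which the first lever press after a fixed interval (FI) elapses is
rewarded, and the interval changes — without any cue — every block of
13–21 trials (FI ∈ {12, 24, 36, 48, 60} s, drawn without replacement). The
scientific question the toolkit addresses is *how fast a subject updates its
timed responding when the interval changes*: rodents on this task adjust
their response start times within one to two trials of an uncued change.

The package provides, as one tidyverse-style pipeline:

1. **A generative simulator** of sFI sessions. The presser is a reduced
   scalar-timing agent: it holds an estimate *ŝ* of the current interval,
   switches from baseline Poisson pressing (rate λ₀) to high-rate pressing
   (λ₀ + λ₁) at a start time *t* ~ Normal(*k·ŝ*, (*w·k·ŝ*)²) truncated below
   at the post-reward consumption pause (*k* = 0.5, the response-threshold
   fraction; *w* the Weber coefficient of variation, i.e. scalar timing
   noise), and after each reward updates
   *ŝ ← ŝ + α (experienced interval − ŝ)* — a delta rule where *α* = 1 is
   one-shot updating.
2. **Four single-trial start-time estimators**, each censored at 5 s:
   the *first press*; the *first burst* (three presses whose inter-press
   intervals fall in the experiment's fastest 40%); the *press-rate
   increase* (first time the 3-s-smoothed per-second rate exceeds 2× the
   session-average rate); and the *change point* (first Bayesian change
   point of the trial's IPI sequence at Bayes factor ≥ 10, exponential
   observation model with conjugate Gamma rate priors, maximised over
   candidate splits).
3. **Block-transition analyses**: previous-block normalisation (100% = no
   change), increase/decrease and small/large transition classes,
   adaptation-latency tests (one-sample vs 100%, Holm-corrected),
   trial-by-trial Pearson correlations of start time with FI duration, and
   blockwise scaling fits (start time ≈ 0.5 × FI).

Everything takes and returns tibbles, results have `tidy()` / `glance()`
methods and `autoplot()` figures, and event logs round-trip through plain
CSV at 1 ms resolution.

## Worked example

```r
library(sfiadapt)

cohort <- simulate_cohort(sfi_protocol(), agent_params(),
                          n_subjects = 8, seed = 42)
st <- estimate_start_times(cohort)
glance(blockwise_scaling(st))
#> # A tibble: 4 × 5
#>   metric        slope intercept r_squared     n
#>   <chr>         <dbl>     <dbl>     <dbl> <int>
#> 1 first_press   0.141      6.45     0.733    40
#> 2 first_burst   0.503      3.04     0.971    40
#> 3 rate_increase 0.499      2.50     0.970    40
#> 4 change_point  0.468      2.17     0.973    40
```

Blockwise mean start times scale linearly with the interval with a slope
near 0.5 for the burst, rate-increase and change-point estimators — the
signature of responding that begins at about half the timed interval. The
first press is much shallower because baseline "lever-sampling" presses
intrude soon after the 5 s censoring point.

```r
rec <- build_transition_records(st, "first_burst")
glance(adaptation_latency(rec))
#> # A tibble: 2 × 3
#>   metric      direction latency
#>   <chr>       <chr>       <int>
#> 1 first_burst decrease        2
#> 2 first_burst increase        2

post_transition_correlations(st, metrics = "first_burst")
#> # A tibble: 4 × 6
#>   metric      post_trial     n      r r_squared  p_value
#>   <chr>            <int> <int>  <dbl>     <dbl>    <dbl>
#> 1 first_burst          1    18 -0.264    0.0696 2.90e- 1
#> 2 first_burst          2    26  0.820    0.672  3.01e- 7
#> 3 first_burst          3    28  0.902    0.814  5.45e-11
#> 4 first_burst          4    29  0.874    0.764  6.00e-10
```

Burst start times deviate significantly from the previous block's mean on
the second trial under the new interval — one reward is enough — and the
correlation between start time and FI duration, absent on the first
post-transition trial (the subject cannot yet know the interval changed),
is strongly positive from trial 2 onward. `autoplot()` on the
`adaptation_curves(rec)` and correlation tables draws the corresponding
figures, and `plot_session_raster()` shows single-session press rasters
with the four estimates overlaid.

A full simulate → estimate → analyse → report run, with every table written
as CSV beside a resolved YAML configuration, is:

```r
run_pipeline(run_config(seed = 7), "out/")
```

or from a shell, `Rscript inst/cli/sfiadapt.R all --seed 7 --out out/`
(subcommands: `simulate`, `metrics`, `transitions`, `report`, `all`).

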