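---
title: "Analysing pyloric rhythm responses to temperature steps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing pyloric rhythm responses to temperature steps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermopyle)
```

`thermopyle` quantifies how the pyloric rhythm of the crustacean
stomatogastric ganglion responds to bath-temperature steps: how fast the
rhythm runs, how constant the relative timing (phase) of the PD, LP and PY
neurons stays, and whether the transition between temperatures is smooth or
"jagged". This vignette is the package's methodological account: the models
and rules each stage implements, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical decisions that make results deterministic.

## From spike times to cycles and phases

The input to everything is a table of spike times labelled by unit. Bursts
are maximal runs of spikes whose internal gaps are all *shorter* than the
inter-burst interval criterion; a gap of at least `burst_min_gap` (default
0.200 s) splits, so a gap of exactly 200 ms starts a new burst. Runs with
fewer than `burst_min_spikes` (default 2) spikes are discarded outright —
they neither form bursts nor merge into neighbours, so stray spikes cannot
perturb cycle boundaries. The same rule is applied to LP and PY by default;
both parameters can be set per call if follower units need different
criteria.

A cycle runs from the first spike of one PD burst to the first spike of the
next; the period is that interval and frequency its reciprocal. Follower
bursts attach to the cycle containing their *onset*; when two bursts of one
unit start inside one cycle only the first is used and the surplus is
counted (never silently dropped), and a burst whose offset extends past the
cycle end keeps its long offset and is flagged (`spill`), yielding offset
phases above 1 rather than truncated values. Phase is event latency from
the cycle start divided by the period, which makes all phase measures
invariant to time translation and uniform rescaling — a property the test
suite checks directly.

Period-matched comparisons (`match_periods()`) pair cycles across two
conditions whose periods differ by at most `period_match_tolerance`
(default 0.02 s, about 2 % of a typical period). The pairing is greedy in
cycle order, taking the nearest unpaired partner. Greedy pairing is not
guaranteed to maximise the number of pairs in adversarial inputs; the tests
therefore validate it against exhaustive search on instances whose
tolerance makes the maximal matching unique, which is the regime the
comparison is meant for. The tolerance is a reportable analysis choice, not
a constant of nature.

## Temperature annotation and steady-state summaries

Each cycle's temperature is the time-average of the linearly interpolated
thermocouple trace over the cycle (trapezoidal integration over the native
samples plus interpolated endpoints). Averaging rather than sampling at the
cycle start matters only at the third decimal during ~0.05 °C/s ramps, but
it fixes the value deterministically for any sampling rate — readers accept
any rate, and nothing downstream assumes one.

Holding windows are maximal contiguous runs of cycles within
`holding_tolerance` (0.3 °C) of a protocol target; a cycle eligible for two
targets goes to the nearer one, and runs shorter than `min_window_cycles`
(10) are discarded because brief transits of the tolerance band during a
ramp are not holds. Targets can be given explicitly or inferred from the
trace by plateau detection (`infer_targets()`: the trace is smoothed over
~15 s, and stretches whose central-difference slope stays below
0.005 °C/s for at least 60 s are plateaus). Repeated visits to one target —
for instance a return to 11 °C at the end of a protocol — are kept as
separate windows and pooled only in the per-target summary, where each
window is labelled, so start-versus-return comparisons remain possible.

Temperature sensitivity is summarised by Q₁₀ under
f(T) = f_ref · Q₁₀^((T−T_ref)/10), with T_ref = 11 °C. `fit_q10()`
estimates it by ordinary least squares of ln f on (T−T_ref)/10 over *all*
holding temperatures, which uses the whole curve rather than its endpoints;
the endpoint estimator (f_high/f_low)^(10/ΔT) is provided separately
(`q10_endpoint()`) because two-point summaries are common in the
literature. The pipeline regresses on each window's *measured* mean
temperature rather than the nominal target: in-band ramp-tail cycles pull
both the window's mean frequency and its mean temperature slightly down
the curve together, so the two cancel, and noiseless simulations are
recovered to ~10⁻⁷ rather than ~10⁻³. With only two points the log-space
residual SD is defined as 0.

## The jag statistic

Non-monotonic transitions are quantified on smoothed per-cycle series:
frequency over `freq_smooth_window` = 30 cycles and temperature over
`temp_smooth_window` = 10 cycles. The moving average is centered with edge
truncation (the window shrinks near the ends, so output length equals input
length); whether the original analyses used centered or trailing windows is
not documented practice, so a trailing variant sits behind
`align = "right"` for sensitivity checks — on these slow signals the choice
moves the conditional probabilities by far less than animal-to-animal
spread. For even windows the extra sample is taken on the trailing side.

Each cycle after the first is classified by its change from the previous
cycle with *strict* inequalities: temperature is `increasing` when the
change exceeds `temp_increase_threshold` (0.01 °C/cycle), frequency
`increasing`/`decreasing` beyond ±`freq_change_threshold` (0.002 Hz/cycle).
A change of exactly the threshold is `stable`, and the tests pin this
boundary bit-exactly. Classification runs over the entire recording — the
state labels themselves define the ramp and hold segments, so no
pre-segmentation is applied. The jag statistics are then the conditional
proportions P(frequency decreasing | temperature increasing) and
P(frequency increasing | temperature stable), with an empty conditioning
set yielding a missing value rather than 0/0. Raising either threshold can
only move cycles toward `stable`, a monotonicity the suite checks.

## Phase constancy and group statistics

For each experiment and phase event, a least-squares line of
per-temperature mean phase (holding-window cycles only) on temperature
gives a slope, reported per °C and per 10 °C; by the advance convention
negative slopes are advances. Across experiments the slopes are tested
against zero with a Shapiro–Wilk gate at `alpha` (0.05): normal → two-sided
one-sample t; otherwise Wilcoxon signed-rank. A one-sample test on slopes
is used even where a paired phrasing appears in the field, since a paired
test of per-experiment values against zero differences is the same test in
this usage. p-values are Bonferroni-multiplied by the number of tests in
the battery; the default multiplier is 10 (5 events × 2 conditions), but
`run_full_analysis()` derives it from the number of tests actually run, so
incomplete designs are not over-corrected. Phase-versus-temperature
relationships need not be strictly linear; the per-event fits carry their
data so curvature can be inspected, but no nonlinear model is fitted.

Condition comparisons use the same normality gate on paired differences
(paired t vs Wilcoxon), a one-way repeated-measures ANOVA with the
within-subjects error term and Tukey HSD via the studentized-range
distribution for three-condition designs, Pearson correlation with the
two-sided t approximation, and Welch's two-sample t by default (pooled
variance behind a flag) where groups are independent. Sidedness is always
two-sided. No sphericity correction is applied by default, matching the
conventional uncorrected df for these small designs; Greenhouse–Geisser
adjustment is available behind `gg_correction`. Degenerate inputs —
zero-variance differences or identical slopes — are errors, not silent
p = 1.

## Voltage-clamp I_h

Because I_h activates slowly, its amplitude during a long hyperpolarizing
step is the difference between the holding current shortly after the step
and at steady state. Both are window means: the initial window defaults to
50–150 ms after onset (past the capacitive transient of a real recording)
and the steady window to the last second of the 12 s step. With a
mono-exponential activation of time constant τ the window means understate
the amplitude by exp(−t/τ) factors that are computable in closed form, and
the tests compare against exactly that analytic value. Note the initial
window is not free: at τ = 2 s a 50–150 ms window already contains ~5 % of
the activated current, so measurements wanting ~1 % accuracy on synthetic
(transient-free) traces should place it within the first ~10 ms, as the
acceptance checks do. Percent block is computed per cell —
100·(1 − blocked/control) — and then averaged; the mean of per-cell ratios
is deliberately *not* the ratio of group means, and a regression test
asserts the two differ where block fraction covaries with amplitude.

## The synthetic generator

The generator exists so that every stage above is testable by parameter
recovery without any recordings. It emulates:

- the step protocol: holds at 11–21 °C in 2 °C increments with ramp + hold
  spanning 240 s. The controller's ramp rate is not standardised, so the
  default ramp is 40 s (configurable); a baseline hold precedes the first
  ramp, and optional Gaussian thermocouple noise affects only the
  *recorded* trace, never the true bath temperature driving the dynamics;
- steady-state frequency scaling f_ss(T) = f_ref · Q₁₀^((T−T_ref)/10);
- jag dynamics as first-order adaptation: x is the warming rate low-pass
  filtered with time constant `jag_tau` (30 s, matching the observed
  ~30 s of transient after each ramp), clipped at zero, and
  f = f_ss − `jag_gain`·x (floored at 0.05 Hz). `jag_gain` is in
  Hz/(°C/s); at the default ramp (0.05 °C/s) a gain of 5 produces
  ~0.2 Hz dips, the magnitude seen in I_h-blocked preparations. The form
  is phenomenological by design — the biophysical hypothesis involves
  I_A kinetics for which no equations are established;
- cycle generation at integer crossings of the integrated instantaneous
  frequency (trapezoidal, 0.05 s grid), so the number of cycles equals the
  floor of the integrated frequency by construction;
- per-unit burst placement at phase parameters with optional linear
  temperature drift, validated for ordering (PD OFF < LP ON < LP OFF)
  across the protocol's temperature range before generation. The PD burst
  spans a fixed duration in seconds (default 164 ms) rather than a fixed
  phase, which reproduces the observed rise of PD OFF phase with
  temperature; passing `pd_burst_duration = NULL` switches to a fixed
  phase. Spikes are evenly spaced within the burst — the analysis uses
  only first and last spikes, so intra-burst structure is fixed merely for
  determinism — and each spike gets independent Gaussian jitter
  (default SD 5 ms);
- a single RNG stream per experiment with documented draw order
  (thermocouple noise, then PD, LP, PY jitter), so a fixed seed gives
  byte-identical output.

What it does **not** emulate: conductance-based dynamics, LP→PD feedback
(condition differences are encoded directly as parameter differences),
spike-sorting errors, missing or extra bursts, intra-burst spike-rate
structure, or non-stationary drift unrelated to temperature. Passing
recovery tests therefore demonstrates that the analysis inverts its own
generative assumptions at realistic noise levels — not that those
assumptions exhaust real recordings.

## Numerical choices and test scale

Results are deterministic: JSON reports are serialised with sorted keys
and 12-significant-digit floats, repeated runs are byte-identical, and a
failing experiment in a batch is isolated and recorded while the rest
complete. Duplicate spike timestamps collapse with a warning; missing
measurements serialise as empty CSV fields, never zeros; readers reject
non-monotone timestamps, non-finite values and unparseable rows (citing
the line number) rather than skipping them.

The test suite validates each primitive against an independent oracle
(brute-force burst grouping on 1000 random trains, brute-force windowed
means, closed-form OLS, textbook ANOVA sums of squares, analytic window
integrals) and runs parameter-recovery sweeps at sizes chosen to keep the
whole suite under a couple of minutes: a 12-point noiseless
(f_ref × Q₁₀) grid recovered to 10⁻³, 24 jittered replicates for estimator
bias (observed Q₁₀ bias well under 0.02), 12 seed-matched pairs for the
control/Cs jag separation, and 1000 simulated families for family-wise
error of the Bonferroni battery. At the grid's fastest corner (4.6 Hz) the
200 ms burst criterion no longer separates bursts of a ~0.2 s period
rhythm, so that sweep uses phase-proportional PD bursts and an 80 ms gap —
the criterion scales with the rhythm it was defined for.

## Limitations

Phases are treated as plain fractions, not circular quantities; this is
appropriate for the observed range (≈0.1–0.9) but would wrap for events
near the cycle boundary. The Q₁₀ model assumes a single exponential over
11–21 °C and will average over any crab-specific departures ("jags" are
excluded from steady-state windows only insofar as the holding-window rule
excludes ramps). The period-matching scheme and the moving-average
alignment are documented conventions, configurable but not derivable from
first principles. Group-level numbers from real cohorts depend on the
recordings themselves; this package reproduces methods and published
worked examples, and verifies the machinery by synthetic recovery.
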