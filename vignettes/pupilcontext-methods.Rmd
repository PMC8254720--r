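---
title: "Methods: contextual pupillometry, from raw traces to Bayes factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contextual pupillometry, from raw traces to Bayes factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilcontext)
```

## The scientific problem

A bright object on a dark screen evokes a pupillary constriction whose
amplitude grows with the light flux it delivers, hence with its size. When
the same object is embedded in an illusory 3D context (a corridor receding
in depth), its *perceived* size changes with apparent distance — objects at
the "far" end look larger than physically identical objects at the "near"
end (size constancy / Emmert's law, of which the Ponzo illusion is the
classic demonstration). If the pupillary light response is driven by the
perceptual representation rather than the raw retinal image, far objects
should evoke deeper constrictions than physically matched near objects, and
the magnitude of that contextual modulation should differ between
individuals — in particular, it should shrink with increasing autistic
traits, which are associated with weaker contextual integration.

`pupilcontext` implements the complete trial-level analysis of such an
experiment: a balanced 100-trial design (5 figurine sizes × 2 corridor
locations × 10 repetitions, in two blocks of 50), 500 Hz eye-tracker trace
cleaning, per-trial response summarisation, mixed-model and correlational
inference with JZS Bayes factors, and a synthetic-data generator that
stands in for human recordings.

## The preprocessing chain

Cleaning follows four sequential steps applied per trial, in this order:

1. **First-trial exclusion.** Trial 1 of each block is dropped before any
   filtering: the corridor background appears abruptly at block start and
   its own pupil response contaminates the first stimulus.
2. **Gross artifact rejection.** Samples with pupil < 0.1 mm, or more than
   1 mm from the *trial median*, are removed. The median is computed once
   over all raw samples of the trial — including samples about to be
   removed — because the deviation rule is defined against the trial's
   median, not against an iteratively re-estimated one.
3. **Velocity excision.** On the surviving samples, speed is the absolute
   pupil change from the retained predecessor divided by the actual elapsed
   time (so gaps left by step 2 do not manufacture spurious speeds). Any
   sample faster than 2.5 mm/s marks a 20 ms epoch for removal, read as
   ±10 ms around the offending sample's timestamp, inclusive; overlapping
   epochs are unioned before removal.
4. **Down-sampling to 10 Hz.** Retained samples are averaged in half-open
   100 ms windows `[k·100, (k+1)·100)` left-aligned at stimulus onset. An
   empty window is *missing* (`NA`), never zero.

Pupil bins become change-from-baseline by subtracting the mean of the
non-missing bins starting before 200 ms (within the light-response
latency); if both baseline bins are missing the trial is invalid
(`no_baseline`). The per-trial response is the mean change over bins from
200 ms to stimulus offset; trials with ≥ 40 % of their 40 bins missing are
invalid (`too_missing`) — the threshold is inclusive ("40 % or more").
Baseline choice: the baseline could equally be computed from the raw 500 Hz
samples of the first 200 ms; both give near-identical values and the
bin-based definition is fixed here (it reuses the same missing-data
semantics as the response window).

Gaze is linearized as degrees from screen centre, `x = (px − 512)·40/1024`,
`y = (px − 384)·30/768`, with y increasing *upward*; readers of
screen-native row coordinates must flip the sign when writing the exchange
TSV. Pupil input is assumed millimetres post-calibration; `read_samples_tsv()`
accepts a scalar `mm_per_unit` standing in for an artificial-pupil
calibration factor.

### A qualification on threshold monotonicity

Tightening the gross-deviation threshold does *not* always reduce the
retained-sample count of the composed chain: a spike with amplitude between
the tight and loose thresholds is removed outright by the tight filter
(1 sample) but at the loose setting survives to trigger a ±10 ms velocity
excision (~11 samples at 500 Hz). Only the per-step claims hold
unconditionally (gross removal sets are nested in the threshold; the
velocity step is monotone in its own threshold for a fixed input). The test
suite asserts both the per-step claims and the explicit counterexample.
The documented robustness rerun (gross threshold 2 mm instead of 1 mm) is a
single config knob and changes per-trial responses only where the two
settings actually removed different samples.

## The synthetic-data generator

The generator is a stated world, not a fit. Its structure:

- **Timeline.** 1 s fixation then 4 s stimulus; traces cover `[0, 4 s)` at
  500 Hz.
- **Perceived size.** Near figurines are the reference (perceived =
  physical height, 7.8° × {0.8, 0.9, 1.0, 1.1, 1.2}). Far figurines are
  inflated by a contextual gain `c(AQ) = c0 · max(0, 1 − β·(AQ −
  AQmin)/(AQmax − AQmin))`, with `c0 = 0.20` and `β = 1.5`, so the pupil
  channel's illusion fades to zero around AQ ≈ 21 and is absent for the
  upper third of the AQ range. Verbal reports use a *separate,
  AQ-independent* gain (0.15): the generator builds in the empirical
  dissociation in which the behavioural illusion is present but unrelated
  to autistic traits while the pupillary modulation is AQ-coupled. With
  `β = 1.5` the low-AQ half of a sample shows contextual constrictions of
  order −0.05 mm while the high-AQ half sits near zero — the regime the
  median-split analysis is designed to resolve.
- **Response model.** Constriction amplitude saturates with perceived area:
  `A(p) = a_max(1 − e^{−g·p²/a_max})`, `g = 0.02` mm/deg², `a_max = 1.2`
  mm. Driving on area reflects light flux; saturation produces the
  size-by-location interaction (the contextual gain buys less extra
  constriction for already-large stimuli). `A` is concave in area
  everywhere and concave in height over the stimulus range (below ~5.5° the
  exponential is still convex in height — irrelevant for 6.2–9.4°
  stimuli). The time course is a unit-peak gamma kernel (shape 3, time
  constant 0.55 s, latency 0.2 s), chosen so the deterministic trace never
  exceeds the 2.5 mm/s velocity threshold and the first 200 ms are an
  uncontaminated baseline.
- **Variability.** Between participants: baseline 4.26 ± 0.7 mm, a
  multiplicative reactivity factor (SD 0.25), a log-normal blink-rate
  multiplier (σ = 0.5). Within participants: trial amplitude jitter (SD
  0.35 mm, truncated so amplitudes stay non-negative), trial baseline
  jitter (0.05 mm), white measurement noise of 1 µm per sample (eye-tracker
  class noise; large white noise would be physically wrong *and* would
  trip the velocity filter on every trial). Report noise is multiplicative
  with Weber fraction 0.15; the report scale is 10 mm/deg (at 57 cm,
  1° ≈ 1 cm, so reports are roughly veridical millimetres).
- **Artifacts.** Blinks: Poisson onsets (0.5 Hz × participant multiplier),
  fixed 500 ms duration, samples forced below 0.1 mm (or to true gaps with
  `blink_as_gap = TRUE`, so both reader branches are exercised); spikes:
  isolated ±2 mm displacements at 0.5 Hz. Ground truth records every
  corrupted index. These rates put the per-trial exclusion fraction at
  roughly 10–20 % across participants, the order of magnitude a strict
  40 %-missing gate produces on attentive adult observers; the generator
  makes no claim to match any particular sample's exclusion rate exactly.
- **Gaze.** Mean offsets (−2, −2)° for near and (+2, +2)° for far (far
  figurines are higher and to the right), plus 0.3°/° of vertical shift
  with figurine height (feet anchored to the corridor floor raise the
  centre of mass of taller figurines) and 0.5° jitter — deviations of
  about 4°, decoupled from the pupil channel.
- **Gender** is recorded (P(female) = 0.66) and given no effect on
  anything, so the gender comparison is a pure null control.

What the generator does **not** emulate: hippus and slow oscillations,
accommodation-driven near responses (deliberately absent — the analysis
checks that baseline pupil is flat across conditions), saccade kinematics,
luminance-dependent noise, or any correlation between AQ and nuisance
parameters (AQ is sampled independently of everything except the pupil
context gain, so any recovered AQ association is attributable to the
planted coupling). A green parameter-recovery test therefore establishes
that the pipeline recovers the stated coupling from data with this
structure — not that real pupil data have this structure.

### Summary-level fast path

`simulate_summaries()` emits per-trial summaries directly (expected
response = −A·k̄ with k̄ the kernel's mean over the response window, plus
the same amplitude/report noise), skipping trace synthesis and
re-cleaning. Artifact-free traces pass the cleaning chain unchanged, so
the two routes share their distribution of valid-trial summaries; a
dedicated test checks the trace route against the fast route trial by
trial in the noise-free limit. Simulation studies (100-dataset parameter
recovery, 200-dataset type-I calibration) use the fast path to stay within
minutes on one CPU; everything trace-dependent is tested on the trace path.

## The inferential layer

- **Mixed models.** `fit_lmm()` fits a participant random intercept by
  REML (lme4) and reports marginal Wald F tests per fixed term with
  sum-to-zero factor coding and residual denominator df (observations
  minus fixed-effect parameters). This df bookkeeping — not
  Satterthwaite — matches the repeated convention of quoting F(k, n−p)
  on trial-level data, and in the zero-between-variance balanced limit the
  F statistics coincide with classical fixed-effects ANOVA to machine
  precision (the verification surface, since trial-level human data are
  not bundled). Degenerate designs (a factor observed at one level, rank
  deficiency) raise errors naming the offending factor.
- **Correlations.** Pearson r with t-based two-sided p and Fisher-z 95 %
  CI. The JZS Bayes factor for a correlation uses the default g-prior
  formulation (unit prior scale) integrated numerically, reported as
  log10(BF10); |lgBF| > 0.5 is read as substantial evidence. The
  two-sample t-test Bayes factor uses the Rouder default scale √2/2 —
  the two conventions reproduce the published operating points
  (r = 0.38, n = 50 → lgBF 0.64; r = 0.04 → −0.94; t(48) = 0.18 at 33 vs
  17 → −0.52) and both scales are exposed as arguments. Integration
  failures raise; there is no silent fallback.
- **Partial correlation** correlates residuals after regressing both
  variables on the covariate. If either residual vector is numerically
  zero (a variable deterministically explained by the covariate), the
  partial correlation is defined as exactly 0 with p = 1, rather than the
  correlation of rounding errors.
- **Contextual effects** are per-participant far-minus-near means over
  valid trials (pooled and per size level); a participant lacking valid
  trials in a location cell is NA and logged. **Median split**: high group
  strictly above the sample median AQ, ties to the low group; per-group
  t-based 95 % CI of the mean effect. **Leave-one-out**: the headline
  pupil-effect-vs-AQ correlation is recomputed after removing the
  participant with the most extreme (most deviant from the mean) pupil
  effect.
- `run_full_inference()` executes the whole battery — size×location and
  AQ×location models on reports and pupil, AQ correlations pooled and per
  size, pupil-vs-report correlation across participant×cell means with
  and without physical size partialled out, baseline-pupil and gaze
  controls, gender t-tests, leave-one-out — deterministically, and the
  bundle serializes to versioned JSON plus CSV tables.

## Numerical and design choices made here

- Block-balanced randomization: each 50-trial block contains 5 repetitions
  of each of the 10 cells, shuffled within block. A fully unconstrained
  shuffle is also reproducible but lets cell counts drift across blocks;
  balance within blocks makes the two half-sessions exchangeable.
- The printed stimulus heights (6.2–9.3° in 0.8° steps) and the
  proportional ±20/±10 % rule disagree in the second decimal; the
  proportional rule generates the design (6.24–9.36°), printed values
  treated as rounded.
- The AQ scoring key is not distributable and is a required input; the
  generator emits total scores directly so no key is needed for testing.
- Near/far locations are treated as a fully crossed factor; whether real
  sessions alternated locations randomly or in runs is not modelled.
- Per-size AQ correlations are reported descriptively; which size shows
  the strongest correlation is a qualitative observation, not a test.
- All simulation entry points restore the caller's RNG state; participant
  sub-streams are derived from the master seed with a 31-bit LCG step, so
  any session is reproducible in isolation.

## Limitations

- The mixed-model F tests use residual df; packages using Satterthwaite or
  Kenward–Roger will print larger p-values at small n. At the trial counts
  this design produces (≈ 3900 valid trials) the difference is immaterial.
- The generator's noise model is a stated assumption. No distributional
  claim about real inter-trial pupil variability is made or needed by the
  tests.
- The acceptance-level recovery checks run at summary level; the trace
  route is verified against the summary route and against a brute-force
  cleaning oracle, but a full 100-dataset trace-level recovery study would
  take hours, not minutes, and is intentionally out of scope.
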