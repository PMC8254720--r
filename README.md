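# pupilcontext

Trial-level pupillometry of contextual size illusions.

## What this is for

The pupillary light response — the transient constriction evoked by a
bright stimulus — scales with stimulus size. When a bright figurine is
shown inside an illusory 3D corridor, a figurine at the apparently *far*
end is perceived as larger than a physically identical one at the *near*
end (size constancy / Emmert's law; the Ponzo illusion). If the pupil is
driven by perceived rather than retinal size, far figurines should evoke
deeper constrictions, and the strength of this contextual modulation
should vary between people — in particular, shrink with increasing
autistic traits (higher Autism-Spectrum Quotient, AQ).

`pupilcontext` is a tested pipeline for exactly this analysis, for
researchers in visual psychophysics and pupillometry:

- **Design & AQ**: the balanced 100-trial session (5 figurine sizes —
  7.8° ± 10/20 % — × near/far × 10 repetitions, two blocks of 50) and
  binary AQ scoring (0–50, clinical cut-off 32).
- **Preprocessing** of 500 Hz eye-tracker traces: first-trial-per-block
  exclusion, gross artifact rejection (pupil < 0.1 mm or > 1 mm from the
  trial median), velocity excision (> 2.5 mm/s, ±10 ms epoch), 10 Hz
  down-sampling into half-open 100 ms windows, baseline correction over
  the first 200 ms, and exclusion of trials with ≥ 40 % missing bins.
- **Statistics**: linear mixed models with participant random intercepts
  (Type-III-style Wald F, residual df), per-participant far−near
  contextual effects, Pearson and partial correlations with Fisher-z CIs
  and base-10 log JZS Bayes factors (`|lgBF| > 0.5` = substantial
  evidence), median-split and gender analyses, leave-one-out robustness.
- **Synthetic sessions**: a generative model in which constriction
  amplitude saturates with *perceived* area,
  `A(p) = a_max (1 − e^{−g p² / a_max})`, perceived far-size is inflated
  by an AQ-coupled contextual gain
  `c(AQ) = c0 · max(0, 1 − β (AQ − AQmin)/(AQmax − AQmin))`, and verbal
  size reports use an AQ-independent gain — plus blinks, spikes, gaze
  offsets and measurement noise, with exact ground truth for every
  corrupted sample.

## Worked example

```r
library(pupilcontext)

cfg <- sim_config(n_participants = 12, seed = 42)   # paper-like preset
ss  <- simulate_summaries(cfg)                      # fast summary-level path
eff <- context_effects(ss$trials, ss$participants)
head(eff[, c("participant_id", "aq", "pupil_effect_mm", "report_effect_mm")], 4)
#>   participant_id aq pupil_effect_mm report_effect_mm
#> 1              1  2    -0.015209610         15.27423
#> 2              2 27     0.008119455         12.66777
#> 3              3  9    -0.057192442         16.28145
#> 4              4 21    -0.041360469         12.98904
```

`pupil_effect_mm` is each participant's far−near contextual pupil effect:
negative values mean deeper constriction for far figurines (the illusion
acting on the pupil). Note the low-AQ participants (AQ 2, 9) showing
sizeable negative effects and high-AQ participants near zero. Reports show
the behavioural illusion (~13–16 mm overestimation at the far end)
regardless of AQ.

```r
r <- pearson_ci(eff$aq, eff$pupil_effect_mm)
r$lgbf <- lgbf_correlation(r$r, r$n)
r
#> r = 0.514 [-0.085 0.840], n = 12, p = 0.0873, lgBF = -0.03
```

The positive correlation (weaker contextual constriction at higher AQ) is
visible but, at n = 12, neither the p-value nor the Bayes factor is
conclusive — at the full preset (n = 50) the planted coupling is recovered
with the correct sign in ~100 % of simulated datasets.

```r
d <- merge(ss$trials[ss$trials$valid, ], ss$participants, by = "participant_id")
d$size <- factor(d$size_level)
fit_lmm(d, "pupil_response_mm", "size * location")
#> Linear mixed model (random participant intercept), n = 1176
#>   size               F(4,1166) = 48.64, p = 7.17e-38
#>   location           F(1,1166) = 9.34, p = 0.0023
#>   size:location      F(4,1166) = 0.92, p = 0.453
```

Physical size and 3D location both modulate the pupil response at the
trial level.

## Command-line pipeline

```sh
Rscript -e 'pupilcontext::cli_main()' simulate --dir out --seed 1 --participants 50
Rscript -e 'pupilcontext::cli_main()' validate --dir out
Rscript -e 'pupilcontext::cli_main()' analyze  --dir out
```

`simulate` writes `samples.tsv` (500 Hz samples), `trials.csv`,
`aq_scores.csv` and a `ground_truth.csv` sidecar; `analyze` preprocesses
every session, writes `trial_summaries.csv` and `exclusion_log.csv`
(every dropped trial with its reason), and a versioned `report.json` with
the full inference bundle plus `cell_means.csv` / `participant_effects.csv`.
The gross-threshold robustness rerun is
`analyze --median-dev-max 2`.

## Documentation

See `vignettes/pupilcontext-methods.Rmd` for the model, every tunable
parameter with units and defaults, what the synthetic generator does and
does not emulate, numerical tie-breaks, and known limitations.
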