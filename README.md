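# gaitsense

Fall-risk screening for lower limb amputees from a single smartphone
worn at the posterior pelvis during a six-minute walk test (6MWT).

People with lower limb amputations fall far more often than age-matched
able-bodied adults, yet fall-risk screening rarely reaches them: their
gait is asymmetric and variable, which defeats the simple step-detection
heuristics built for elderly gait, and manual labelling of foot strikes
from sensor traces is too slow for the clinic. `gaitsense` implements
the full computational chain that turns a raw 6MWT smartphone recording
into a fall-risk classification:

1. **Preprocessing** — linear re-interpolation to a uniform 50 Hz and a
   fourth-order zero-lag Butterworth low-pass filter (4 Hz cutoff),
   realized with the exact squared Butterworth magnitude response
   |H(f)|² = 1 / (1 + (f/f_c)⁸).
2. **Foot-strike detection** — per-frame labels (1 = foot strike
   present) from either a rule-based labeller (an anterior-posterior
   (AP) acceleration peak immediately followed by a vertical
   acceleration peak) or a trainable sequence labeller (a
   class-weighted random forest over a sliding window of all sensor
   channels).
3. **Post-processing corrections** — runs of consecutive predictions
   collapse to the AP peak; an *adaptive locking period* (half the
   dominant step period, estimated from the first 5 s of vertical
   acceleration, clamped to 10–35 frames) suppresses extra predictions;
   gaps longer than 1.5× the preceding step are searched (shrunk by
   half the locking period at each end) and a missed strike is
   inserted at the AP peak; sides alternate from the medio-lateral
   sway sign.
4. **Features** — each step contributes 62 features: 5 temporal
   (cadence, right/left step time, stride time, and the symmetry index
   SI = |t_R − t_L| / (½(t_R + t_L)) × 100), 27 descriptive statistics
   and 30 spectral descriptors (quartile/maximum/SD/peak-distinction of
   the FFT magnitude spectrum and REOH, the even-to-odd harmonic power
   ratio, for six channels). Per participant, the min, max, mean and SD
   over all included steps give 248 features.
5. **Classification** — correlation-based feature selection (CFS merit
   k·r̄cf / √(k + k(k−1)·r̄ff), best-first search) inside each fold of a
   leave-one-out cross-validated random forest (100 trees, majority
   vote), reported as a confusion matrix with accuracy, sensitivity and
   specificity (fall risk positive).

Because clinical 6MWT recordings of amputees are not publicly
available, the package ships a synthetic gait generator
(`generate_walk()`, `generate_cohort()`) producing 6-minute, 50 Hz
walks along a 20 m hallway with periodic 180° turns, known ground-truth
foot strikes, left/right step-time asymmetry and additive sensor noise,
so every stage is testable end to end.

## Worked example

```r
library(gaitsense)

walk <- generate_walk(gait_sim_params(duration = 120, cadence = 96,
                                      step_time_asymmetry = 1.15,
                                      noise_sd = 0.2, seed = 42))
rec    <- preprocess_recording(walk$recording)
labels <- events_to_labels(label_rule_based(rec), nrow(rec))
events <- postprocess(labels, rec)
events
#> <foot_strike_events> 191 event(s)
#>   frame time_s  side
#> 1    26   0.50  left
#> 2    59   1.16 right
#> 3    89   1.76  left
#> ...

steps <- step_features(rec, events)
sprintf("mean cadence %.1f steps/min, mean symmetry index %.1f%%",
        mean(steps$cadence), mean(steps$symmetry_index))
#> "mean cadence 96.3 steps/min, mean symmetry index 12.9%"
```

The 191 cleaned strikes alternate sides; turn steps are excluded, so
175 of 190 step windows survive, each with its 62 features. The
recovered cadence matches the simulated 96 steps/min, and the 1.15
right/left step-time ratio appears as a ~13% symmetry index
(SI = 2 × 0.15 / 2.15 ≈ 14%, reduced slightly by frame quantization).

A cohort goes through selection and classification the same way:

```r
cohort <- generate_cohort(cohort_spec(n_fall_risk = 10,
                                      n_no_fall_risk = 14,
                                      duration = 60, seed = 7))
res <- run_pipeline(pipeline_config(seed = 7), cohort)
res$report
#> <classification_report>
#>   confusion (rows actual, cols predicted):
#>                  no_fall_risk fall_risk
#>   no_fall_risk             14         0
#>   fall_risk                 1         9
#>   accuracy 95.8%, sensitivity 90.0%, specificity 100.0%
```

A thin command-line wrapper with `simulate`, `preprocess`,
`train-detector`, `detect`, `features`, `classify` and `run`
subcommands lives at `inst/cli/gaitsense`.

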