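# ppgtrend

Automatic discrimination between **hypovolemia** (blood loss, BL) and
**euvolemia** (no blood loss, NBL) from multi-channel photoplethysmogram
(PPG) recordings. The package is aimed at physiological-signal researchers
working on early hemorrhage detection — settings (trauma care, intraoperative
monitoring, combat casualty care) where heart rate and blood pressure stay
deceptively normal until a critical fraction of blood volume is lost, while
the pulsatile amplitude of the PPG begins to fall much earlier.

## Method

For each recording sampled at 80 Hz:

1. **Channel selection.** Of the simultaneously recorded PPG channels, keep
   the one with the minimum histogram Shannon entropy
   `H = -Σ p_b log2 p_b` — an inverse proxy for signal quality.
2. **Time–frequency analysis.** Extract 2-minute sequences along the
   recording; within each sequence slide a 1-minute window in 10-second
   steps (7 windows). Each window gets a high-resolution time–frequency
   spectrum by **variable-frequency complex demodulation (VFCDM)**: a first
   pass demodulates at fixed centers spaced `Fw = 0.5` Hz apart, a second
   pass re-demodulates along each band's instantaneous-frequency trajectory
   with the narrower cutoff `Fv = 0.15` Hz.
3. **AM_HR trend.** In each window, take the spectral maximum over the
   heart-rate band (0.66–3 Hz) at each time sample and average: the window's
   heart-rate-band amplitude. Averaging the 7 windows gives one mean
   **AM_HR** value per sequence; plotting these against time and fitting an
   ordinary least-squares line yields the 4-feature vector
   `(r², slope, % change, signed change)`. Negative trends indicate blood
   loss, positive ones euvolemia.
4. **Classification.** An RBF-kernel SVM `K(x,y) = exp(-γ‖x−y‖²)` is
   evaluated under a deliberately conservative protocol: undersample the
   majority class to balance (e.g. 65 NBL + 29 BL → 29 + 29), repeat the
   balancing 10 times, permute each balanced dataset 10 times, and run
   stratified 4-fold cross-validation in each of the 100 runs for every cell
   of a γ grid (7 values) × C grid (58 values: 0.01 and 1·10^i, 2·10^i,
   5·10^i for i = 0…18). Overall accuracy, sensitivity and specificity are
   averaged per cell; the optimal cell maximizes mean overall accuracy.

A seeded synthetic PPG generator (pulse with peak-aligned harmonics,
respiratory modulation, baseline wander, per-channel noise, and a
configurable linear decay of the heart-rate-band envelope) makes the whole
pipeline testable without clinical data.

## Worked example

```r
library(ppgtrend)

# a blood-loss-like record: HR-band envelope decays 50% over 10 minutes
rec <- simulate_record(sim_config(duration_s = 600, amp_decay_frac = 0.5,
                                  seed = 11), label = "BL")
res <- featurize_record(rec)
res$features
#> trend features: r2 = 1.0000, slope = -8.349e-04 /s, pct_change = -42.26%, abs_change = -0.4012
```

The fitted AM_HR trend is strongly linear (r² ≈ 1.0) and negative: the
heart-rate-band amplitude lost ≈ 42% between the first and last sequence,
the signature of progressive volume loss. (The −42% rather than −50% is
expected: the first and last AM_HR points sit at the centers of the first
and last 2-minute sequences, not at the record's endpoints.)

```r
cohort   <- simulate_cohort(cohort_spec(seed = 1))   # 29 BL / 65 NBL preset
features <- featurize_cohort(cohort)
result   <- run_experiment(features, experiment_config(seed = 1),
                           reduced_param_grid())
summary(result)
#> RBF-SVM grid-search experiment: 7 x 8 grid, 100 runs/cell (10 resamples x 10 permutations, 4-fold CV, scaling: none)
#> optimal cell: gamma = 0.001, C = 0.01 -> OA 100.00%, sensitivity 100.00%, specificity 100.00%
```

On the default synthetic cohort the classes are well separated by
construction (BL envelope decays 30–60%, NBL drifts within ±5%), so the
protocol saturates; on clinical data the same protocol reports its accuracy
per (γ, C) cell in exactly the same way.

There is also a command-line interface (installed under `exec/`):

```sh
ppgtrend run-all --seed 1 --out demo/          # simulate -> features -> classify
ppgtrend entropy --record demo/cohort/sim_001.csv
ppgtrend classify --features demo/features.csv --grid gamma=0.001:C=2 --out res.json
```

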