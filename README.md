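# cardiocycle

Detecting the cardiac signature of epileptic brain activity from single-lead
ECG. Epileptic discharges perturb autonomic control of the heart, deforming
the morphology of individual cardiac cycles — often before any overt heart
rate change. `cardiocycle` implements a cycle-morphology classification
pipeline for that signal, built around *statistical cycles* and
*median-centered moment features*, plus a seeded synthetic-ECG generator so
that every stage is testable without clinical data downloads.

The pipeline:

1. **Condition** the raw signal: resample to 256 Hz, zero-phase Butterworth
   bandpass (default 0.5–40 Hz, order 4), amplitude-normalize to unit peak,
   trim 1% of samples from each end.
2. **Locate R-peaks**: annotation files when present (WFDB `.atr` or plain
   `.rpeaks` sidecars), otherwise the Pan–Tompkins detector (bandpass →
   derivative → squaring → moving-window integration → adaptive dual
   thresholds with search-back, 200 ms refractory).
3. **Segment** into statistical cycles: fixed windows of
   L = round(fs·(λ+θ)) samples spanning λ = 0.4 s before to θ = 0.6 s after
   each R-peak (λ + θ ≤ 1 s).
4. **Featurize** each cycle with moments about a center c — classical
   (c = mean x̄) or robust (c = median η):

   σ_c² = (1/N) Σᵢ (xᵢ − c)²,  ψ_c = (1/N) Σᵢ (xᵢ − c)³ / σ_c³,
   κ_c = (1/N) Σᵢ (xᵢ − c)⁴ / σ_c⁴.

   The median variant (σ_η², ψ_η, κ_η) resists impulsive artifacts
   (powerline bursts, muscle activity, electrode motion) because the median
   stays anchored to the isoelectric baseline while the mean chases
   deflections. A `raw = TRUE` flag gives the unnormalized (no 1/N)
   convention.
5. **Classify** cycles healthy vs. epilepsy with a small MLP (one hidden
   layer of 5/10/100 neurons, ReLU + Adam, lr 0.01, ≤ 1000 epochs, log loss)
   under patient-grouped 10-fold cross-validation, reporting accuracy,
   sensitivity (epilepsy = positive) and specificity as mean ± sd across
   folds. Mean- and median-centered runs share identical folds for paired
   comparison.

## Worked example

```r
library(cardiocycle)

rec <- synth_record(synth_config(duration = 120, class_label = "epilepsy",
                                 seed = 42))
rec
#> <ecg_record> subject synth-42 (epilepsy)
#>   30720 samples @ 256 Hz (120.0 s), amplitude in [-0.928, 1.22]
#>   r_peaks: 188 annotated

pre   <- preprocess_record(rec)
peaks <- get_r_peaks(pre, "always_detect")   # ignore annotations: detect
cs    <- segment_cycles(pre, peaks)
cs
#> <cycle_set> subject synth-42 (epilepsy): 183 cycles x 256 samples
#>   (R at column 103), 2 dropped at boundaries

head(extract_features(cs, "median"), 3)
#>   subject_id    label  center variance skewness kurtosis
#> 1   synth-42 epilepsy -0.0469   0.0141     3.38     16.0
#> 2   synth-42 epilepsy -0.0312   0.0152     3.00     12.6
#> 3   synth-42 epilepsy -0.0312   0.0126     2.90     13.2
```

Each row summarizes one 1-second cycle: at 95 bpm a window holds more than
one beat, and deformed/overlapping cycles show the elevated variance and
shifted higher moments the classifier feeds on. The full experiment on the
default synthetic corpus (10 + 10 subjects × 100 cycles = 1,000 + 1,000
cycles, master seed 1):

```r
res <- run_pipeline(run_config(center_kind = "both", seed = 1))
res$median
#> <eval_report> cv, median-centered features, 10 fold(s)
#>   accuracy    0.97 ± 0.03
#>   sensitivity 0.96 ± 0.04
#>   specificity 0.97 ± 0.02
#>   confusion   TP=962 FN=38 TN=974 FP=26
#>   per-subject majority-vote accuracy 1.00
```

Accuracy/sensitivity/specificity are cycle-level metrics aggregated over the
10 patient-grouped folds (no subject ever appears on both sides of a fold);
the majority-vote line is the per-subject aggregation. Real recordings are
read with `read_record()` (WFDB header/signal/annotation triplets or
two-column CSV).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end experiment from scratch at the given
seed — generates the synthetic corpus, preprocesses, detects R-peaks,
segments, extracts both feature families and evaluates the MLP under
patient-grouped 10-fold CV — printing both evaluation reports and writing the
machine-readable result map to `--out`.

## Documentation

The methods vignette (`vignettes/cardiocycle-methods.Rmd`) documents the
model and its assumptions, all tunable parameters, the numerical choices
(filter realization, window rounding, moment conventions), what the
synthetic generator does and does not emulate, and known limitations.
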