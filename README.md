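# physioload

Physiological correlates of cognitive load from fNIRS and EEG.

## The problem

During demanding visuomotor work — the motivating setting is
laparoscopic-surgery training — an operator's spare mental capacity is
traditionally measured with questionnaires (NASA-TLX) and secondary-task
performance (reaction time to randomly timed beeps, non-response rate).
Both interrupt the work they measure. Cardiac and ocular physiology offer
continuous, unobtrusive alternatives:

* **HR** — instantaneous heart rate, extracted here from the cardiac
  pulsation carried by continuous-wave fNIRS optical signals
  (Beer–Lambert conversion, 0.5–2 Hz band-pass, zero-crossing beat
  periods, interpolation to the acquisition grid);
* **HRV** — the high-frequency share of heart-rate spectral power,
  `HRV = HF / (HF + LF)` with LF = 0.01–0.15 Hz and HF = 0.15–0.8 Hz: a
  normalized index in [0, 1] of respiratory sinus arrhythmia, which
  shrinks under load;
* **BR** — spontaneous blink rate (resting norm ≈ 14/min), extracted from
  multi-channel EEG by artifact cleaning, zero-phase FIR filtering,
  downsampling, ICA, automatic blink-component identification (frontal
  dominance + source kurtosis) and adaptive peak detection.

Per-episode features (mean/SD/max/min of HR and HRV, mean BR) predict the
workload measures through Pearson correlation, multivariate regression
summarised as `R_adj = sqrt(|adjusted R^2|)`, quadratic fits probing an
inverted-U (Yerkes–Dodson) performance law, and a cascade-forward neural
network (hidden layers 10 and 8, Levenberg–Marquardt training) scored by
`R_CV` — the mean, over repeated five-fold cross-validations, of the
Pearson correlation between out-of-fold predictions and actual values.

Human recordings of this kind are not freely redistributable, so the
package includes a first-class synthetic-session generator
(`simulate_cohort()`) with complete ground truth — RSA-modulated cardiac
dynamics, Mayer-wave and drift confounds, frontally weighted blink
transients in 1/f EEG, and behaviour linked to latent load — against
which every stage is validated. See the methods vignette
(`vignettes/methods.Rmd`) for the models, parameters and design
decisions.

## Worked example

Simulate a 16-subject cohort, extract features through the optical
cardiac chain, and build the prediction-performance table:

```r
library(physioload)

cfg  <- simulation_config(n_subjects = 16, seed = 42,
                          layout = default_session_layout(task_s = 120))
co   <- simulate_cohort(cfg, include_eeg = FALSE)
ex   <- lapply(co, extract_subject_features)
tabs <- assemble_feature_target_tables(
  do.call(rbind, lapply(ex, `[[`, "features")),
  do.call(rbind, lapply(ex, `[[`, "targets")))
pt <- build_prediction_table(
  tabs$features, tabs$targets,
  target_cols = c("nasa_tlx_avg", "reaction_time", "completion_time"),
  spec = cf_net_spec(hidden_sizes = c(4, 3), max_iter = 25),
  repeats = 20, seed = 7)
pt[, c("target", "hr_mean_r", "hrv_mean_r", "br_mean_r", "R_adj", "R_CV")]
```

```
          target hr_mean_r hrv_mean_r br_mean_r R_adj R_CV
    nasa_tlx_avg      0.56      -0.58     -0.12  0.80 0.71
   reaction_time     -0.24       0.60     -0.84  0.88 0.73
 completion_time      0.36      -0.52      0.60  0.85 0.93
```

Each row is one workload target over the pooled task episodes (48 rows =
16 subjects × 3 tasks). The per-feature columns are Pearson correlations:
subjects with higher mean heart rate and lower HRV respond *faster* to
the secondary task (negative and positive r, respectively), while
subjective load rises with heart rate — the sign structure the generator
builds in and the analysis must recover. `R_adj` uses all nine features
in one regression; `R_CV` is the cross-validated correlation of the
cascade-forward net, which here exceeds most single-feature correlations
because the features carry complementary information.

The EEG blink pathway runs the same way from raw synthetic EEG:

```r
bt  <- simulate_blink_times(14, 300)                   # ground truth
eeg <- synthesize_eeg(bt, simulation_config(), 300)
out <- eeg_blinks_chain(eeg, nc = 10, est_subsample = 3, seed = 1)
blink_rate(out$events, c(0, 300), out$eeg$removed_intervals)  # ~14/min
```

A full simulate → extract → predict → report run with caching and a
manifest is available as `run_pipeline()` (or
`Rscript inst/cli/cogload.R run --out dir`).

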