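---
title: "Models and methods: physiological correlates of cognitive load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: physiological correlates of cognitive load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`physioload` implements a complete analysis chain for tracking cognitive
load during demanding visuomotor work (the motivating setting is
laparoscopic-surgery training) from two non-cerebral physiological
channels:

* **cardiac** — instantaneous heart rate (HR) and a spectral heart-rate
  variability index (HRV) extracted from the cardiac pulsation carried by
  continuous-wave fNIRS optical signals, and
* **ocular** — blink events and blink rate (BR) extracted from
  multi-channel EEG via independent component analysis.

Per-episode features computed from these series are then related to
subjective and behavioural workload measures (NASA-TLX scores,
secondary-task reaction time and non-response rate, task completion time,
error counts) through Pearson correlation, multivariate linear regression
summarised as $R_{adj}$, quadratic fits probing an inverted-U
(Yerkes–Dodson) performance law, and a cascade-forward neural network
scored by repeated five-fold cross-validated correlation $R_{CV}$.

Because human recordings of this kind are not freely redistributable, the
package ships a synthetic-session generator with complete ground truth.
Every stage of the pipeline is validated against that ground truth; this
vignette records the models, the tunable parameters, and the design
decisions behind both the analysis and the generator.

# The cardiac pathway

## Optics to hemoglobin

Raw data are optical-density series from dual-wavelength optode pairs.
`convert_beer_lambert()` applies the modified Beer–Lambert law: for each
pair, the $2 \times 2$ extinction system at the two wavelengths is solved
per sample for oxy- and deoxyhemoglobin concentration changes, using the
source–detector distance and a differential pathlength factor (default
6). The extinction table (`extinction_coefficients()`) covers 690, 760,
830 and 850 nm. The simulator forward-mixes with the same table, so the
round trip is exact to numerical precision when noise is off — this
algebraic identity is one of the test suite's oracles.

## Cardiac waveform and beat periods

`extract_cardiac_waveform()` band-passes each oxyhemoglobin channel in
the cardiac band (0.5–2 Hz) and averages across channels. The filter is a
fourth-order Butterworth applied forward and backward (zero phase). A
windowed-sinc FIR would serve equally; the Butterworth realisation was
chosen for its short warm-up at the 10 Hz fNIRS rate, and its stop-band
attenuation at 0.1 Hz (Mayer-wave band) exceeds 20 dB, which the tests
verify against an FFT oracle.

`detect_beat_periods()` finds zero crossings of the band-passed waveform
with linear interpolation between bracketing samples. The interval
between every other crossing — i.e. between consecutive same-direction
crossings — is one beat period, timestamped at the midpoint. Because both
crossing directions are used, overlapping period estimates arrive at
roughly twice the beat frequency, which slightly smooths the series.
Periods outside $[0.3, 2.0]$ s are discarded; the gate mirrors the design
band and protects against dropped or doubled crossings in noise.

`heart_rate_series()` converts periods to bpm ($60/T$) and linearly
interpolates the beat-midpoint values onto the regular acquisition grid,
with constant extrapolation at the record edges (a convention; the edges
contribute a negligible share of any episode).

## The HRV index

For a mean-removed HR segment, `compute_band_powers()` integrates a
Hann-tapered periodogram over a low-frequency band (0.01–0.15 Hz) and a
high-frequency band (0.15–0.8 Hz, enveloping normal respiration); the
boundary bin at 0.15 Hz belongs to HF. The index

$$\mathrm{HRV} = \frac{HF}{HF + LF} \in [0, 1]$$

measures the share of heart-rate variability driven by respiration
(respiratory sinus arrhythmia, RSA), which shrinks under sympathetic
activation and cognitive load. Only Fourier-resolvable bins (multiples of
$1/T$) enter the integrals, so for windows shorter than 100 s the LF band
is under-resolved; this is intrinsic to short-window spectral estimation
and is documented rather than hidden. A plain Hann periodogram is used
rather than Welch averaging because segments are short and the index is a
band-power *ratio*, which cancels most of the estimator variance.

Two segmentations are computed: a sliding window (default 30 s length,
1 s step) for time courses and within-episode statistics, and the whole
episode as a single segment where a scalar per episode is wanted. The
per-episode feature set (mean, SD, max, min of HRV) is computed from the
windowed series, since order statistics of a single number are
degenerate.

# The ocular pathway

EEG processing follows the conventional blink-artifact chain, run here
*for* the artifact rather than against it:

1. **Epoch baseline correction** (`baseline_correct_epochs()`): per
   channel and episode, the epoch mean is subtracted (the whole epoch is
   its own baseline).
2. **Cleaning** (`clean_eeg()`): consecutive 1000 ms windows in which any
   channel exceeds ±200 µV are excised and logged; channels whose sample
   excess kurtosis exceeds 5 afterwards are rejected (background EEG has
   near-zero excess kurtosis). Excised intervals are carried through the
   chain so that event times and blink-rate denominators refer to
   original session time and effective (retained) duration.
3. **Filtering and decimation** (`filter_downsample_eeg()`): a zero-phase
   Hamming windowed-sinc FIR band-pass, 0.16–40 Hz, applied by FFT
   convolution with group-delay compensation, then decimation to 200 Hz.
   The kernel length follows the Hamming design rule
   $L \approx 3.3/\Delta f \cdot f_s$ with the transition width defaulting
   to the lower band edge; the 40 Hz cut-off anti-aliases the 200 Hz
   output rate by construction.
4. **ICA** (`decompose_ica()`): the unmixing is estimated by FastICA
   (`ica::icafast`) by default; extended Infomax (`ica::icaimax`,
   `method = "imax"`) is available behind the same contract. The contract
   is what the tests pin down: sources reconstruct the centred data
   (exactly at full rank), and on synthetic data containing a rank-one
   blink pattern some component's topography matches the true spatial
   pattern with $|r| > 0.95$. For long records the unmixing can be
   estimated on every $k$-th sample (`est_subsample`) and applied to all
   samples; components can be restricted (`nc`) to the leading principal
   subspace, which the high-variance blink source always inhabits.
5. **Blink-component identification**
   (`identify_blink_components()`): a deliberately simple, fully
   automatic surrogate for template-based artifact classifiers. A
   component is flagged when (a) its topography is frontally dominant
   (mean absolute weight over the frontal channels at least twice that of
   the rest) and (b) its source is temporally spiky (excess kurtosis
   above 3). Both scores are returned for inspection, and thresholds are
   arguments. The full feature set of published classifiers (spatial
   average difference, generic discontinuity measures, EM-fitted
   thresholds) is out of scope: with synthetic ground truth available,
   the two-feature surrogate is sufficient to validate the blink-rate
   pathway, which is the quantity of scientific interest here.
6. **Event detection** (`detect_blink_events()`): the spikiest flagged
   source is sign-aligned (blinks point upward), and local maxima above
   `median + 4 MAD` separated by at least 200 ms become blink events.
7. **Blink rate** (`blink_rate()`): events per effective minute within an
   episode, where effective duration excludes excised fragments.

Blink *rate* is the only per-episode ocular feature: blinks are too
sparse (resting norm ≈ 14/min) for meaningful within-episode statistics
beyond the mean.

# Feature and target tables

`episode_summary_features()` reduces the HR and HRV series to mean, SD,
max and min within each episode, plus the episode blink rate — nine
features per subject × episode. `secondary_task_metrics()` computes the
behavioural targets from the stimulus/response log: reaction time is the
mean latency over responded stimuli (median selectable), and a stimulus
counts as *non-responded* when no response arrives before the next
stimulus onset (a late response is a non-response; the final stimulus has
no successor and only needs any response).

`assemble_feature_target_tables()` pools the task episodes (one row per
subject × task episode) and aligns features with targets on exact keys;
unmatched rows are dropped with a warning, never silently imputed. The
predictor source is selectable — task episodes (default), the subject's
first rest episode, or task-minus-rest changes — mirroring the
re-analyses that ask how much of the predictive signal is carried by
resting physiology alone.

Outliers are flagged by the quartile-fence rule with whisker constant
$w = 2$: values outside $[q_1 - w \cdot IQR,\; q_3 + w \cdot IQR]$, with
quartiles by linear interpolation of order statistics (R type 7). Flagged
values are reported but *not* removed before modelling; removal is a
caller decision.

# Prediction

For each target, `build_prediction_table()` emits the per-feature Pearson
$r$ with its two-sided $p$ (significance marked at $p < 0.05$ per cell,
deliberately without multiplicity correction — the table is descriptive,
not a family of confirmatory tests), the multivariate OLS summary
$R_{adj} = \sqrt{|R^2_{adj}|}$ (the absolute value because adjusted $R^2$
can be negative under the null), and the cross-validated correlation
$R_{CV}$ of the cascade-forward network.

## The cascade-forward network

The network has two sigmoidal hidden layers (default sizes 10 and 8) and
a linear output, with *cascade* connections: the input feeds every layer
directly, and the first hidden layer also feeds the output. Inputs and
target are range-scaled to $[-1, 1]$ with training-fold statistics.
Training minimises squared error by Levenberg–Marquardt: the package
supplies the forward pass and an analytic Jacobian of the outputs with
respect to all weights, and delegates the trust-region iteration to
MINPACK (`minpack.lm::nls.lm`). Because the default net has more weights
(288 for nine inputs) than a cross-validation training fold has rows
(~74), the residual vector is augmented with $\sqrt{\lambda}\,w$ terms —
a light ridge penalty ($\lambda = 10^{-3}$) that both regularises the
underdetermined problem and satisfies MINPACK's requirement of at least
as many residuals as parameters. Training is deterministic given the
spec's seed. No hyperparameter search is performed; the architecture is a
fixed, conventional choice.

## Repeated cross-validated correlation

`cross_validated_correlation()` draws a random five-fold partition,
trains on four folds (all scaling fitted on training rows only), predicts
the held-out fold, and — after all five folds — computes one Pearson
correlation between the pooled out-of-fold predictions and the actual
values. This is repeated (default 100 partitions; 1000 for full-scale
runs) and $R_{CV}$ is the mean. Repeats with degenerate constant
predictions are excluded and counted.

Two statistical facts about this estimator are worth recording. First,
out-of-fold prediction removes optimism from *overfitting*, but not the
dataset-level chance correlation between noise features and the target:
under a null target with $n = 93$, the per-dataset $R_{CV}$ is centred at
zero with spread of roughly $1/\sqrt{n} \approx 0.1$. Calibration checks
therefore average $R_{CV}$ over several independent null datasets; a
systematic positive bias would indicate information leakage, and the
measured bias is below 0.02 in magnitude. Second, pooling out-of-fold
predictions before correlating (rather than averaging per-fold
correlations) follows the convention of the motivating analysis.

## Quadratic fits

`fit_quadratic()` regresses a target on $(1, x, x^2)$ and reports the
overall F-test $p$-value ($p_2$) plus a *U-shape flag*: quadratic
coefficient positive and vertex inside the observed predictor range. The
flag operationalises the detection of a within-range performance optimum
(the inverted-U law relating arousal and performance — completion time is
the performance *cost*, so the fitted curve opens upward).

# Group comparisons and descriptive machinery

`compare_groups()` dispatches the Wilcoxon signed-rank test for paired
samples (zero differences dropped — the standard convention, flagged when
all differences are zero) and the two-sample Kolmogorov–Smirnov test for
unpaired ones. Both are exact where R's implementations provide exactness
at the sample sizes involved. A discreteness caveat applies to
calibration experiments: the exact two-sample KS test's attainable level
at $\alpha = 0.05$ wobbles with $n$ (0.0396 at $n = 31$ per group, 0.0467
at $n = 60$), so calibration checks use group sizes whose attainable
level sits near the nominal 5 percent rather than at a discreteness
trough.

`timecourse_summary()` smooths per-subject series with a centred 10 s
moving average (shrinking at edges), aligns subjects at episode start and
separately at episode end, and aggregates the first/last 40 s across
subjects — task episodes differ in duration across subjects, so only the
edges are comparable. `rest_task_shift()` regresses the rest-to-task
change of a metric on its resting value: a flat fit means the shift is
level-independent; a slope near $-1$ is the regression-to-the-floor
signature of a bounded metric.

`boxplot_stats()` and `render_report()` produce the descriptive tables
(quartiles, $w = 2$ whiskers, outliers) and write a deterministic report
directory with an MD5 manifest.

# The synthetic-session generator

`simulate_cohort()` generates, per subject: latent standard-normal
*aptitude* (skill) and *tonic arousal trait*; a truncated-normal resting
heart rate ($\mathcal{N}(70, 8^2)$ bpm on $[45, 100]$); per-episode
latent load as a logistic function of task difficulty minus aptitude plus
noise; and from these, fully ground-truthed signals:

* **True heart rate**: base level plus load effect (default +10 bpm per
  unit load), approached exponentially with a 30 s time constant (heart
  rate ramps at task onset); an RSA oscillation at the respiration
  frequency (0.25 Hz) whose depth (resting default 0.06 of base) shrinks
  with load and is floored near zero; a 1.5 bpm low-frequency
  (baroreflex/Mayer-band, 0.1 Hz) oscillation; and a slow random-walk
  drift. The LF oscillation matters: the HRV index is a ratio, and
  without genuine low-frequency heart-rate power it saturates at 1
  regardless of RSA depth. RSA depth switches instantly at episode
  boundaries while the HR level ramps — reproducing the observed
  asymmetry in task-onset time courses.
* **fNIRS optics**: per optode pair, a cardiac oxyhemoglobin oscillation
  whose phase is the integral of true HR (with a weak second harmonic),
  a Mayer-wave sinusoid, random-walk drift and white noise, forward-mixed
  into two wavelength channels via Beer–Lambert.
* **Blinks**: a Poisson-like process with a 0.5 s refractory period, at a
  rate (resting default 14/min) lowered by load and raised by the tonic
  trait.
* **EEG**: per-channel 1/f background plus a stereotyped ~300 ms biphasic
  blink transient at each blink time with a frontally weighted rank-one
  topography (so ICA can isolate it), ~120 µV at the frontopolar sites
  against a 15 µV background.
* **Behaviour**: secondary-task beeps at uniform 3–10 s intervals with
  500–1000 ms durations; response latencies lognormal, shifted up by load
  and down by the tonic trait, with a miss probability increasing in
  load; NASA-TLX dimension scores linear in load, discretised to steps of
  5 in $[0, 100]$; completion time quadratic in an arousal variable (load
  plus a share of the trait) about an optimum — the inverted-U
  performance law; Poisson error counts increasing in load.

## Why two latent dimensions

A single load variable cannot reproduce the empirical sign pattern that
pooled task episodes exhibit: mean HR correlating *negatively* and mean
HRV *positively* with reaction time, while blink rate also correlates
negatively with reaction time. If one latent drove everything, the
blink-rate/reaction-time correlation would have to share the sign of the
heart-rate pathway. The generator therefore separates (a) episode-level
task load — raising HR, suppressing RSA and blinks, slowing responses and
raising subjective load — from (b) a between-subject tonic
arousal/engagement trait — raising HR, shallowing RSA, *raising*
spontaneous blink rate and *speeding* responses. Pooled across subjects,
the trait dominates the feature–reaction-time covariances and yields the
observed sign triple; within a subject, episode contrasts retain the load
directions. Both dimensions are plausible physiology: spontaneous blink
rate tracks dopaminergic arousal upward even though task attention
suppresses it.

## What the generator does not emulate

Motion artifacts and optode-coupling changes in fNIRS; non-blink EEG
artifacts (saccades, EMG, line noise); heteroscedastic or non-stationary
background spectra; learning curves within an episode; missing data other
than excised fragments; and any cortical hemodynamic or oscillatory
brain-activity signal (brain activity is explicitly out of scope).
Passing the recovery tests therefore demonstrates correctness of the
implementations under the stated signal model, not robustness to every
artifact class of real recordings.

# Problem sizes and numerical choices

Validation runs use desk-scale sizes chosen once: 10-subject cohorts for
HR recovery (episode-mean RMSE < 2 bpm); 100 replicates for the RSA-depth
discrimination of the HRV index; 20 replicates of the full EEG chain at
1000 Hz / 19 channels / 5-min records for blink-rate recovery within
±10 percent of the realized blink count (the 2000 Hz default is exercised
in unit tests; the chain is rate-agnostic above the anti-alias bound);
100 31-subject cohorts for sign-structure recovery; cross-validation with
100 repeats and a reduced 4–3 hidden-layer net for calibration
experiments, the full 10–8 net being the analysis default; 10,000 null
simulations for test calibration. The single global seed fans out to
every stage through a deterministic hash (`derive_seed()`), so all
results are exactly reproducible.

Degenerate inputs are handled by undefined markers (`NA`) rather than
errors where the quantity is legitimately undefined (HRV with zero total
power, blink rate over a fully excised episode, correlation of a
zero-variance feature), and by errors where the call is a usage mistake
(records shorter than the filter warm-up, windows longer than the record,
unmatched subject keys).

# Known limitations

* The beat detector assumes the band-passed cardiac component dominates;
  severe optical noise produces dropped beats that the period gate
  masks but cannot repair.
* The HRV index inherits the spectral resolution of its window; windowed
  values below ~1/30 Hz resolution mix slow LF power into the DC bin and
  are slightly biased toward HF.
* The blink-component surrogate assumes a frontally dominant, spiky blink
  source; pathological montages (no frontal channels) are rejected
  rather than guessed at.
* $R_{CV}$ on a single dataset carries irreducible chance spread of about
  $1/\sqrt{n}$; comparisons of $R_{CV}$ across targets on one cohort
  should respect that uncertainty (the per-repeat spread is reported).
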