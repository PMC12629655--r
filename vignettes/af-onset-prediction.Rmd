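---
title: "Forecasting atrial fibrillation onset from heart-rate variability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting atrial fibrillation onset from heart-rate variability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Paroxysmal atrial fibrillation (AF) announces itself: in the hour before an
episode, autonomic tone shifts, short-term vagally mediated heart-rate
variability (HRV) rises, premature atrial contractions (PACs) become more
frequent, and the beat-to-beat rhythm becomes more fragmented. `afonset`
implements a complete desk-scale rendition of the analysis that exploits
this: starting from beat-annotated RR-interval recordings (24-h Holter
style), it selects labelled sinus-rhythm analysis windows, computes a
45-feature HRV battery on overlapping 5-min segments, classifies segments
with tree ensembles under temporal patient-grouped cross-validation,
aggregates predictions to the recording level, and ranks features by exact
Shapley attribution.

Because clinical Holter databases cannot be shipped with a package, a
first-class synthetic RR-cohort generator reproduces the statistical
structure the analysis assumes. Everything downstream of the generator is
agnostic to where the beat annotations came from.

## Data model and window eligibility

A recording is three pieces: a per-beat table (`time_s`, `rr_ms`, `label`
with labels `N`/`PAC`/`ARTIFACT`), a rhythm annotation (AF episodes as
onset/offset pairs, each at least 30 s — the conventional AF definition
floor), and metadata (patient, date, age, sex, duration). The plain-text
dialect (`read_beats()`/`write_beats()`) round-trips exactly.

Window eligibility mirrors standard pre-AF study design
(`selection_criteria()`):

* a **pre-AF window** requires an AF onset at least 2 h into the recording,
  at least 60 min of AF-free, dropout-free sinus rhythm immediately before
  the onset, and at least `max(300, af_duration_tier)` seconds of AF after
  it. Episode-duration tiers of 30/300/600 s select increasingly sustained
  episodes; 300 s (the "> 5 min" tier) is the default: sustained
  episodes are the clinically actionable ones, and 30-s episodes are too
  close to the AF definition floor to give stable labels.
* an **NSR window** comes only from arrhythmia-free recordings: one window
  at the first beat and one at hour 12 (the middle of a 24-h recording),
  each emitted only when fully covered by beats.

Two genuinely open design points are resolved as follows. First, the
analysis window is the *first 30 min* of the pre-onset hour
(`input_segment_s = 1800`), leaving a silent ≥ 30-min gap before onset —
this gives the forecast a non-trivial horizon; setting
`input_segment_s = 3600` reproduces the full-hour variant, and the window
always starts at `onset − 3600 s` either way. Second, any inter-beat gap
longer than 5 s inside a candidate window disqualifies it: Holter lead-off
dropout must not silently shrink NN counts.

Age strata use half-open intervals `<60, [60,70), [70,80), ≥80` — the
exhaustive, non-overlapping reading of the conventional clinical strata.

## Preprocessing

An interval is **normal-to-normal (NN)** only when both endpoint beats are
labelled `N`; the intervals into and out of a PAC or artifact beat are
excluded, because ectopic timing contaminates every autonomic statistic.
Retained intervals outside 200–4000 ms are dropped as R-wave double-counts
or missed beats. Windows with fewer than 30 NN intervals are flagged
non-analyzable.

Spline interpolation is applied *only* where uniform sampling is
mathematically required: the six frequency-domain features are computed on a
4-Hz tachogram obtained by natural cubic-spline interpolation of the NN
series (linear extrapolation at the edges, values clamped to the
physiological range). All discrete, beat-to-beat families — time-domain,
geometric, Poincaré, SODP, PRSA, fragmentation — are computed on the cleaned
NN sequence with no gap filling, because their semantics (sign changes,
successive differences, anchor alignment) are defined on true beat-to-beat
transitions, not on resampled curves. 4 Hz is the standard choice whose
Nyquist frequency (2 Hz) comfortably covers the HF band.

## The feature battery

45 features in six families (`af_feature_names()`); the conventions below
are fixed so that every value is unambiguous and testable against
independent direct-formula oracles.

* **Time domain (16).** mean HR; SDNN, SDSD as *sample* SDs (n−1); RMSSD
  with the plain mean inside the root, per its verbatim definition; CVNN,
  CVSD; pNN10/20/50 as proportions with a *strict* inequality ("differing by
  more than"); min/max/median and the 20th/80th percentiles by
  linear-interpolation (type-7) quantiles; TINN and the HRV triangular
  index from a histogram with 7.8125-ms (1/128 s) bins anchored at zero —
  the standard geometric-HRV convention. TINN is the base width of the
  least-squares triangular fit; the search runs over bin centres bracketing
  the mode and the squared error separates into independent ascending and
  descending parts, so the fit is exact and fast.
* **Frequency domain (6).** Welch averaged periodogram of the tachogram
  (Hann taper, 512-sample segments ≈ 128 s, 50% overlap, per-segment mean
  and linear-trend removal), one-sided density scaling so that the
  integrated spectrum recovers the variance (Parseval); band powers by
  trapezoidal integration over LF 0.04–0.15 Hz, HF 0.15–0.4 Hz, total
  0.0033–0.4 Hz; `lf_nu = LF/(LF+HF)` and its complement; LF/HF with a
  finite sentinel of `1e6` when HF is exactly zero (files must never
  contain `Inf`).
* **Poincaré (6).** SD1 is the uncentered root mean square of
  `Δnn/√2` (n denominator), which makes `sd1 = rmssd/√2` an exact algebraic
  identity; SD2 is the population SD of `(nn_i + nn_{i+1})/√2`. With a
  nonzero mean successive difference a centered SD1 would differ — for a
  linear ramp the uncentered SD1 is `step/√2`, not 0 — and the package
  deliberately keeps the identity exact rather than the centered reading.
  CSI and CVI follow the Toichi convention with axes `T = 4·SD1`,
  `L = 4·SD2`: `csi = L/T`, `cvi = log10(L·T)`. The "modified CVI" is
  computed as specified, `log10(T²·L/T)`, which reduces algebraically to
  CVI; it is retained for schema compatibility and documented as redundant.
* **SODP (7).** Strict quadrant counts of consecutive `Δnn` pairs (points
  on an axis belong to no quadrant) and CTM20/50/100, the proportion of
  points strictly inside the respective circle.
* **PRSA (6).** Deceleration anchors `nn_i > nn_{i−1}`, acceleration
  anchors the reverse; capacity `(X(0)+X(1)−X(−1)−X(−2))/4` on the aligned
  average, which reports DC positive and AC negative. Note that on a pure
  period-2 alternans series this window straddles exactly one period and
  the capacity is identically zero — a property worth knowing when
  interpreting fragmented rhythms. The "modified" variants restrict anchors
  to relative changes ≤ 5% (ectopy protection); `ack`/`ddck` use a
  k-interval wavelet (k = 4), `(Σ₀..ₖ₋₁X − Σ₋ₖ..₋₁X)/(2k)`. Window
  half-width, anchor filter and k are package conventions, config-exposed.
* **Fragmentation (4).** On the sign sequence of `Δnn` (zeros inherit the
  previous nonzero sign; leading zeros the first nonzero): PIP is the
  fraction of consecutive sign pairs that flip; acceleration/deceleration
  segments are maximal constant-sign runs, IALS their inverse mean length,
  PSS the fraction of differences in runs shorter than 3; PAS is the
  fraction of NN intervals inside alternation segments — stretches of
  per-beat sign flips spanning at least 4 NN intervals. Adjacent
  alternation segments can share a boundary interval, so PAS counts the
  *union* of covered intervals.

Families whose preconditions fail (PRSA on a constant series, spectra
without 120 s of tachogram) are missing-flagged as `NA`, never fatal.

## Segmentation, dataset assembly, and the classifier

Windows are divided into overlapping 5-min segments
(`segment_spec()`: 300 s length, 60-s stride → 26 segments per 30-min
window, 56 per hour). The stride is a package choice — only "overlapping"
is externally fixed — and 60 s multiplies usable rows by an order of
magnitude while keeping neighbouring segments 80% redundant, which the
recording-level aggregation then absorbs. Segments with fewer than 30 NN
intervals are dropped (counted in the `dropped_segments` attribute).

`fit_predict_cv()` evaluates a gradient-boosted tree (xgboost) or a
probability random forest (ranger) under **temporal patient-grouped 10-fold
cross-validation**: patients ordered by their earliest recording date
(deterministic tie-break on patient id) are cut into contiguous blocks;
every recording of a patient lives in its patient's fold, so repeated
patients can never leak between train and test. Missing features are
imputed with training-fold medians only. Learner hyperparameters are the
libraries' defaults with a fixed seed; there is no tuning loop: with
collinear features and abundant segments, default tree ensembles are
already at ceiling on this task, and a tuning loop would only invite
optimistic bias.

Segment probabilities are averaged per window, window means per recording
(`aggregate_to_recording()`), and the metric suite
(`classification_metrics()`) reports AUROC (Mann–Whitney rank statistic),
AUPRC (step-integrated precision–recall), and the threshold-0.5 confusion
family, each with 95% percentile-bootstrap CIs over recordings (1000
resamples, seeded; single-class resamples are redrawn and counted). The
bootstrap unit is the recording because segments within a recording are
strongly dependent; resampling at any finer unit would
understate the uncertainty.

`shapley_attribution()` produces exact path-dependent TreeSHAP values for
the gbt engine via xgboost's `predcontrib`, per fold on that fold's test
segments, so every segment is explained out of fold; additivity
(attributions + base = margin) holds to float precision. Random forests are
rejected with an explicit unsupported-model error rather than silently
approximated.

## The synthetic cohort generator

The generator (`generate_recording()`, `generate_cohort()`) is a
deliberately minimal mechanism that induces the discriminative structure
the analysis assumes. It is a stand-in for clinical data, not a physiological
simulator.

Sinus rhythm integrates an instantaneous RR model,

    rr(t) = mean_rr + lf_amp·sin(2π·0.095·t + φ_LF)
                    + hf_amp·sin(2π·0.25·t + φ_HF) + ε(t),

beat times by `t_i = t_{i−1} + rr(t_{i−1})/1000` (a chunked fixed-point
iteration, three vectorized passes; the modulation is ≤ 6% of the mean RR so
the iteration contracts rapidly). Key choices:

* **Noise is AR(1)** (lag-1 coefficient 0.8, marginal SD 10 ms). White
  per-beat noise would give *healthy* recordings a pathological baseline
  fragmentation (PAS ≈ 0.4), because independent noise flips the sign of
  successive differences constantly; serially correlated noise restores the
  low-fragmentation healthy baseline that makes fragmentation a meaningful
  pathological marker.
* **Phases are random per recording.** Phase-locking every recording's
  respiration to the recorder start would create spurious systematic
  differences between NSR windows (always at fixed clock positions) and
  pre-AF windows (at random onsets).
* **PACs are Poisson events** (0.2/min baseline): the premature beat lands
  at 0.7·RR after its predecessor and the following sinus beat keeps its
  time, i.e. a compensatory pause that preserves sinus phase. PAC beats are
  labelled and therefore excluded from NN statistics downstream.
* **The pre-onset hour** of an AF recording carries three perturbations:
  the HF amplitude is boosted ×1.8 (vagal surge); the PAC rate ramps
  linearly to ×5 over the final 2 h; and **alternans bursts** cover on
  average 25% of beats in geometric-length runs (mean 8 beats). Inside a
  burst the respiratory modulation is suspended and the RR alternates
  ±12 ms around the local mean with attenuated noise: fragmentation is
  frequent *small-amplitude* sign reversal, not large RR swings. The 12-ms
  amplitude is the smallest that alternates reliably against the residual
  LF slope and noise; large-amplitude bursts would instead be detected by
  pNN50 and the CTM radii and defeat the purpose of injecting a
  fragmentation-specific signal.
* **AF itself** is serially uncorrelated Gamma RR (mean 0.75 × sinus RR,
  CV 0.2), one episode per AF recording with onset uniform in
  [3 h, duration − 1 h] and duration 15–60 min, so every generated episode
  passes the default eligibility rules.
* **Between-patient heterogeneity.** Cohorts draw per-patient resting RR
  (SD 60 ms), modulation and noise scales (lognormal, σ_log 0.3/0.25), and
  per-patient pre-AF phenotype — the strength of the vagal surge
  (mean-preserving lognormal on the boost excess, σ_log 0.35) and the
  alternans burden (Beta around 0.25, concentration 8). A cohort of
  identical patients is both unrealistic and degenerate (every feature
  separates perfectly); heterogeneous phenotypes are what make the learning
  problem non-trivial and the feature ranking meaningful. About 10% of
  patients receive a second recording to exercise the patient-grouped fold
  rule.

`effect_size_report()` is the generator's calibration instrument: under the
default parameters the standardized mean difference (pre-AF vs NSR
segments) exceeds 0.5 for both `rmssd` (vagal axis) and `pas`
(fragmentation axis), and a null generator (boost 1, no alternans, flat PAC
rate, no between-patient jitter) leaves every feature within ±0.2 of zero.

What the generator does **not** emulate: circadian rhythm, respiratory
frequency drift, sleep stages, real artifact/noise morphology, multiple AF
episodes per recording, atrial flutter, and any ECG waveform content.
Passing tests on this cohort therefore demonstrate that the pipeline
recovers *known injected structure* — they say nothing about clinical
performance on real Holter data, and clinically reported discrimination
figures are not reproduction targets for this package.

### A note on attribution under collinearity

The feature battery is heavily collinear by construction: `sd1` is exactly
`rmssd/√2`, `cvsd` is RMSSD normalized by the mean RR, and half a dozen
features (PIP, PAS, PSS, pNN10, SODP Q2/Q4, the CTM radii) all detect
alternans. Boosted trees need only one representative per correlated group,
and TreeSHAP assigns credit to the representative actually used — which
seed-to-seed is `cvsd` rather than `rmssd`, or `sodp_q4`/`pip` rather than
`pas`. On this generator the attribution ranking reliably recovers the two
injected *axes* (every top-5 feature is a short-term-vagal or a
fragmentation detector, with `sd1_sd2` — a member of both worlds — usually
near the top), but the specific representative within an axis is not
stable. This mirrors the known behaviour of Shapley values on correlated
features and is worth remembering when reading published top-5 lists.

## Problem sizes and runtime

The package's own experiments use the default cohort: 120 AF + 120 NSR
24-h recordings (~110,000 beats each), yielding 9,360 five-minute segments
with 45 features — about 90 s to generate and featurize and a few seconds
to cross-validate on a single CPU. The test suite uses smaller cohorts
(6–14 recordings, 6–14-h durations) for unit-level checks and the full
default cohort across five seeds for the end-to-end recovery experiment;
`scripts/acceptance.R` re-runs one full cohort per invocation.

## Numerical conventions, in brief

Sample SD (n−1) for SDNN/SDSD; uncentered n-denominator for SD1; strict
inequalities for pNNx and CTM; 7.8125-ms histogram bins; natural-spline
tachogram at 4 Hz; Welch with Hann/512/50%; percentile bootstrap over
recordings; threshold 0.5; `1e6` sentinels instead of infinities; every
stochastic step takes an explicit seed and the generator is bit-for-bit
reproducible.

## Known limitations

* The generator's mechanisms are linear-additive and stationary within
  regimes; it cannot probe robustness to non-stationarity or artifact
  morphology.
* PRSA variant definitions (`ac_modified`, `ack`, `ddck`) and the
  CSI/CVI/"modified CVI" conventions vary across the literature; the
  package's choices are documented above and config-exposed, but other
  software may report different values for the same series.
* Attribution ranks of individual features are unstable under collinearity
  (see above); axis-level interpretation is the supported reading.
* Recording-level aggregation assumes all windows of a recording share a
  label; cohorts mixing pre-AF and NSR windows within one recording are out
  of scope.
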