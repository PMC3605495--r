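---
title: "Grading neonatal background EEG: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading neonatal background EEG: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(neograde)
```

## The problem

After a hypoxic-ischaemic insult at birth, the background EEG of a term
neonate passes through characteristic stages as cortical function recovers:
from electrical inactivity, through burst suppression with progressively
shorter interburst intervals (IBIs), to continuous activity with
discernible sleep states. Clinicians summarise an hour of background EEG
with a four-level abnormality grade:

| grade | cerebral function | key features |
|---|---|---|
| 1 | normal / mildly abnormal | continuous, 30-50 µV, sleep-wake cycling |
| 2 | moderately abnormal | discontinuous, IBI ≤ 10 s, disrupted cycling, asymmetry |
| 3 | majorly abnormal | IBI 10-60 s, attenuation below 30 µV, no cycling |
| 4 | inactive | activity below 10 µV, or IBI ≥ 60 s |

`neograde` implements an automated grading system for this scale, plus a
synthetic-EEG simulator that generates recordings with known grade so every
stage of the system can be validated without access to clinical data.

## The signal model

The background EEG is modelled multiplicatively,

$$\mathrm{EEG}(t) = a_m(t)\,X(t),$$

where $X(t)$ is a coloured random process whose shaping filter has a
power-law amplitude response $1/f^{\alpha(t)}$ ($\alpha > 1$), and $a_m(t)$
is a slowly varying, non-negative amplitude-modulation (AM) envelope. The
decomposition is only identifiable under the constraint that $a_m$ varies
much more slowly than $X$; under that constraint the envelope carries the
amplitude/continuity information a clinician reads (bursts, suppression,
trace alternant) while the instantaneous frequency (IF) of $X$ carries the
spectral-slope information.

Both sub-signals are estimated from a quadratic time-frequency
distribution $\rho(t,f)$ — a two-dimensionally smoothed Wigner-Ville
distribution (WVD) of the analytic associate $z(t)$ of the epoch:

$$a_m(t) = \Big(\int \rho(t,f)\,df\Big)^{1/2}, \qquad
  f_i(t) = \frac{\int f\,\rho(t,f)\,df}{\int \rho(t,f)\,df}.$$

For a stationary band-limited power-law process on $(f_1, f_2)$ the mean
frequency has a closed form,

$$f_i = \frac{(f_2^{2-2\alpha} - f_1^{2-2\alpha})(1-2\alpha)}
             {(f_2^{1-2\alpha} - f_1^{1-2\alpha})(2-2\alpha)},
  \qquad \alpha > 1,$$

implemented in `powerlaw_if()` (validated against numerical quadrature to
1e-6 relative) and inverted numerically by `estimate_alpha()`.

```{r powerlaw}
powerlaw_if(1.5, f1 = 2.5, f2 = 32)
estimate_alpha(powerlaw_if(1.5, 2.5, 32), 2.5, 32)
```

## Computing the distribution: two paths

`wigner_ville()` implements the discrete WVD through the
instantaneous-autocorrelation + FFT-over-lag construction with zero
extension at epoch edges; its frequency integral reproduces the
instantaneous power $|z(t)|^2$ exactly (to machine precision) by
construction. `smooth_tfd()` then convolves with a separable unit-mass 2-D
Hamming kernel (default 1 Hz × 1 s, i.e. a bandwidth-duration product
BT = 1).

Two numerical facts shaped the design here:

* A BT ≥ 1 kernel makes the smoothed WVD *approximately* non-negative, but
  with a separable Hamming kernel at BT = 1 the residual cross-term ripple
  is of order a few percent of the peak on tones and larger on noise
  epochs. `smooth_tfd()` therefore returns the raw smoothed values
  (reporting the minimum in an attribute) rather than pretending exact
  positivity.
* The grading pipeline needs a strictly non-negative distribution at scale
  (hundreds of thousands of epoch-channels in a cross-validation). Because
  a spectrogram is itself a quadratic TFD with a positive kernel of
  comparable support, `tfd_spectrogram()` computes a spectrogram-form
  distribution whose Hamming analysis window (1.5 × the kernel duration,
  calibrated once against the explicit smoothed-WVD path) matches the
  separable kernel's smoothing. The two paths agree on what the pipeline
  consumes — the AM sub-signal to within a few percent relative L2 and the
  IF to a fraction of a hertz — and the test suite asserts exactly that,
  rather than a map-level identity the cross-terms make unattainable.

The distribution is energy-normalised so that its frequency integral
tracks $|z(t)|^2$; the AM is therefore in microvolts. IF moments are taken
over `[high-pass cutoff, 32] Hz`, the analysis band of the system.

```{r amif, fig.height = 4}
x <- make_colored_noise(64 * 64, 64, noise_model(alpha = 2, f1 = 0.5, f2 = 32),
                        seed = 1)
env <- make_envelope(64, 64, envelope_spec("burst_suppression",
                                           baseline_amplitude = 3,
                                           burst_amplitude = 25,
                                           mean_ibi = 15, ibi_jitter = 3,
                                           ibi_range = c(10.5, 59)),
                     seed = 2)$envelope
autoplot(extract_am_if(tfd_epoch(env * x, 64), f_range = c(0.5, 32)))
```

## The pipeline

1. **Pre-processing** (`preprocess_record()`): linear-phase FIR high-pass
   (windowed-sinc Hamming design; the order follows
   `3.3 * fs / transition_width`, giving 1690 at 256 Hz for the default
   0.5 Hz transition), group-delay compensated, applied *before*
   anti-aliased decimation to 64 Hz; segmentation into epochs with 50%
   overlap, discarding a trailing part-epoch. The cutoff (default 2.5 Hz)
   and epoch length (default 64 s) are the tunable parameters, searchable
   in [0.5, 3] Hz and [8, 64] s.
2. **Features** (`extract_features()`): per channel, the first four
   time-moments of AM and IF, their covariance, relative delta power
   (0.5-4 Hz over 0.5-32 Hz), EEG skewness and kurtosis (non-excess
   convention — a Gaussian gives 3), and the interburst interval;
   channel-combined by the median (the injury is assumed global). Two
   inter-hemispheric features are computed once per epoch: a spectral
   symmetry index, mean over frequency of |L-R|/(L+R) of the
   hemisphere-average spectra, and envelope synchrony, the maximum (and
   its lag, bounded at ±10 s) of the normalised cross-correlation of the
   hemisphere AM envelopes.
3. **Normalisation** (`boxcox_fit()`/`boxcox_apply()`): per-feature
   Box-Cox power transform, λ by profile maximum likelihood on
   offset-shifted training values, then centring/scaling to zero mean and
   unit variance. Training statistics only; apply-time data reuse them.
4. **Classification** (`fit_pairwise()`, `classify_epoch()`): one Fisher
   linear discriminant per unordered pair of the six EEG states (1S1,
   1S2, 2S1, 2S2, 3, 4 — grades 1-2 subdivide into quiet/indeterminate S1
   and active/awake S2). The closed form `w ∝ Sw⁻¹(µᵢ - µⱼ)` is
   ridge-stabilised when the pooled scatter is near-singular. Each pair
   votes for the class whose projected centre is nearer in scatter-scaled
   distance; the most-voted state wins, with vote ties broken by the
   smallest accumulated scaled distance and then the lower-numbered state.
5. **Post-processing** (`merge_states()`, `majority_vote()`): states merge
   to four grades, the hour's modal grade is reported, and a modal
   fraction of at least two thirds marks the decision *certain*. Modal
   ties resolve to the more severe grade — the clinically conservative
   choice.

## The synthetic-data generator

`simulate_record()` composes the same model the features assume:
per-channel unit-variance coloured noise under a shared per-hemisphere
envelope. The defaults encode the grade definitions:

* grade 1 — S2 continuous at 40 µV; S1 trace alternant (50/25 µV
  alternation, ~5 s phases); α = 1.5;
* grade 2 — discontinuous with IBI drawn to stay ≤ 10 s (suppression
  10-13 µV, bursts 35 µV), S1 more discontinuous than S2; α = 1.5; a
  hemisphere amplitude ratio of 0.8 models the grade's clear asymmetry;
* grade 3 — burst suppression, bursts 25 µV (< 30 µV attenuation),
  suppression 3 µV, IBI truncated-normal with mean 30 s clipped into
  (10, 60) s; α = 2.0;
* grade 4 — inactive: flat-spectrum noise rescaled so the record's peak
  stays below 10 µV.

Burst onsets follow a jittered renewal process (the grade definitions give
only IBI bounds, not a distribution) with 0.5 s raised-cosine ramps so the
envelope is slowly varying relative to the carrier, as the model requires.
S1/S2 alternate on a square schedule, by default 30 min + 30 min within an
hour; for shorter simulated recordings `simulate_corpus()` sets the cycle
period to the record duration, preserving the half-and-half state
proportion. Per-subject amplitude scales are log-normal (sd 0.1).

What the generator does *not* emulate: sharp waves, spikes and seizures
(excluded from background grading by definition), hypothermia-modified
EEG, realistic inter-channel propagation, and non-stationary α(t) within a
state. Passing end-to-end tests on this corpus therefore bounds
*implementation* error — the corpus is separable by construction — and
says nothing about clinical performance on real recordings.

## Numerical and design choices

* **IBI detector.** The published system delegates IBI estimation to an
  external burst detector; `estimate_ibi()` is a documented stand-in:
  suppression is a run of the AM below a threshold (default 15 µV, at
  least 1 s), the per-channel IBI is the median run length, channels
  combine by median. Inside the feature pipeline the threshold adapts to
  `max(3, 0.5 · Q90(AM))` because the 2.5 Hz high-pass scales AM roughly
  five-fold below raw-EEG amplitudes; 3 µV is the post-filter equivalent
  of the raw 15 µV rule. A fully suppressed epoch reports the epoch
  length; a continuous epoch reports a flagged 0.
* **Symmetry.** The revised brain symmetry index's exact construction is
  not reproduced; the implemented index keeps its core — normalised
  left-right spectral difference averaged over the band — and maps to
  [0, 1].
* **Median at feature level.** Features are computed per channel and then
  median-combined (rather than combining signals first); this matches the
  burst-detection precedent the channel-combination rule cites and keeps
  inter-channel amplitude differences visible to the symmetry feature.
* **Training subsample.** Classifier training uses artefact-free epochs
  only, capped at 7 minutes' worth per recording (random under a fixed
  seed, scattered rather than contiguous), mirroring the published
  training protocol; validation grades whole recordings including
  artefact epochs.
* **Cross-validation.** `loso()` holds one subject out per fold;
  `grid_search_preproc()` and `backward_elimination()` run a nested LOSO
  strictly inside the training fold, so the held-out subject can never
  influence parameter or feature selection (a canary test asserts this).
  Search deadlocks break on the per-epoch kappa, then towards the smaller
  epoch and lower cutoff. Grid steps are dyadic epochs {8, 16, 32, 64} s
  × cutoffs {0.5, 1, ..., 3} Hz: the ranges are prescribed, the steps are
  ours, and the published optimum (64 s, 2.5 Hz) is on-grid.
* **Kurtosis** is non-excess (Pearson) throughout; the convention is
  documented rather than assumed.
* **Degenerate inputs.** Zero-variance series flag skewness/kurtosis as
  `NA`; zero-power epochs flag relative delta power and symmetry as 0;
  constant envelopes flag synchrony; a zero TFD column interpolates the
  IF and flags it. Fisher fits add a ridge `1e-6 · tr(Sw)/d` only when
  the plain solve fails.

## Problem sizes used in validation

The test suite and the acceptance script validate on deliberately modest
problem sizes chosen to exercise every code path: unit tests use 2-4
minute records and 16-32 s epochs; the end-to-end recovery experiment
trains on 40 ten-minute recordings (10 per grade) and grades 20 held-out
ones at the default operating point (64 s epochs, 2.5 Hz cutoff); the
canary cross-validation uses 6 subjects with a two-point epoch grid. On
this corpus the system recovers the four-grade truth essentially
perfectly (accuracy ≥ 90%, kappa ≥ 0.85 are the asserted floors), which
is the expected outcome for a separable corpus and should be read as an
implementation check, not a clinical claim.

## Known limitations

* The AM-envelope correlation ceiling on burst-suppression data is set by
  carrier amplitude flicker within bursts (~0.85 for a full-band α = 2
  carrier); the pipeline's high-pass widens the carrier's effective
  bandwidth and lifts it above 0.9. Heavier smoothing would raise it
  further at the cost of envelope time resolution.
* The simulator's grade separation makes backward elimination
  under-determined: many feature subsets achieve the same (perfect)
  kappa, so selected subsets on synthetic corpora are not informative
  about which features matter clinically.
* EDF support covers the single-rate multi-channel case the pipeline
  needs, not the full EDF+ event model; annotations travel in sidecar
  text files.
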