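---
title: "From photons to workload: the fnirsbci online pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From photons to workload: the fnirsbci online pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsbci)
```

# The problem

Prefrontal functional near-infrared spectroscopy (fNIRS) measures cortical
hemodynamics with a headband of light emitters and detectors: each *optode*
records back-scattered light at two near-infrared wavelengths (730 and
850 nm), where oxygenated and deoxygenated hemoglobin absorb differently.
A passive brain-computer interface (pBCI) built on such a sensor tries to
infer an operator's mental state — here, *working-memory load* during an
auditory readback task — from single 30 s trials, online, with no more
training data than the first half of the session.

`fnirsbci` implements that pipeline end to end:

1. **Hemodynamics** — raw intensities to concentration changes via the
   modified Beer-Lambert law (mBLL);
2. **MACD filtering** — causal band-pass filtering of every channel by a
   difference of exponential moving averages;
3. **Protocol** — constrained trial-sequence generation, session timeline,
   task-locked segmentation;
4. **Classification** — per-subject linear SVM trained on ten labeled
   trials with cross-validated regularization, then applied one trial at a
   time;
5. **Statistics** — peak responses, ROI averages, effect sizes, exact
   binomial chance thresholds;
6. **Synthesis** — a generative model of a whole session with known ground
   truth, so every stage is testable without recordings.

# Signal model

## Modified Beer-Lambert law

For optode $o$ and wavelength $\lambda$, the optical-density change
relative to a 10 s rest baseline with mean intensity $I_0$ is
$\Delta OD(\lambda) = -\log_{10}\!\big(I(\lambda)/I_0(\lambda)\big)$,
positive when absorption increases.  The mBLL relates it linearly to
chromophore concentration changes:

$$\Delta OD(\lambda) =
  \big(\varepsilon_{HbO_2}(\lambda)\,\Delta[HbO_2]
     + \varepsilon_{hHb}(\lambda)\,\Delta[hHb]\big)\, d \cdot \mathrm{DPF},$$

with source-detector separation $d$ = 2.5 cm and differential pathlength
factor DPF = 5.97, so the effective pathlength is 14.925 cm.  Two
wavelengths give a 2×2 system solved per optode and sample;
concentrations are reported in µmol/L.  The extinction coefficients at
730/850 nm are not dictated by the hardware and differ slightly between
published compilations; the bundled defaults (390/1102.2 and
1058/691.32 cm⁻¹ M⁻¹) are from a standard spectrophotometric table and
can be overridden in the device profile.  A different coefficient table
rescales each channel linearly — downstream classification is invariant
to such a rescaling, which the test suite checks via the rotation /
linearity properties of the SVM stage.

## MACD band-pass filter

Each Δ[HbO₂] / Δ[hHb] channel is filtered online by the difference of a
short and a long exponential moving average (EMA).  With window length
$N$ samples and weight $\alpha = 2/(N+1)$:

$$y_n = \alpha x_n + (1 - \alpha) y_{n-1}, \qquad
  \mathrm{MACD}(x) = \mathrm{EMA}_{N_s}(x) - \mathrm{EMA}_{N_\ell}(x).$$

Windows are specified in seconds — 6 s short, 13 s long — and converted
as $N = \mathrm{round}(w \cdot f_s)$: 12/26 samples at 2 Hz, 24/52 at
4 Hz.  Each EMA has unit DC gain, so their difference rejects DC exactly;
the closed-form transfer magnitude
$|H(f)| = |H_s(f) - H_\ell(f)|$ with
$H(f) = \alpha / (1 - (1-\alpha)e^{-i2\pi f/f_s})$ rises from 0 at DC to
an interior maximum near 0.035 Hz and decays toward Nyquist.  Measured on
steady-state sinusoids at 2 Hz, a 0.002 Hz drift is attenuated about
23-fold (gain 0.044) while a 0.1 Hz in-band signal passes at gain 0.247,
a 5.6:1 preference; the closed form and simulated gains agree within 1%,
which the tests assert at ten frequencies.

Initialization seeds both EMAs with the first sample (configurable to
zero), so a constant stream maps to exactly zero output from the first
sample and there is no startup transient.  The filter is causal: the
output at sample $n$ uses samples $1..n$ only, verified by truncation
equivalence.

# Session protocol

A session is 20 trials, 10 per load level, laid out after a 10 s rest
baseline.  The label sequence is drawn uniformly (by rejection sampling,
cheap because the space is small) over sequences satisfying two
constraints: the first 10 trials contain 5 of each load, and no load
repeats on more than two successive trials.  For odd first-block lengths
(e.g. one trial per class) exact balance is impossible and
floor/ceiling counts are accepted.

Each trial window is 30 s, anchored at message onset, half-open
$[t_0, t_0 + 30)$ with 0-based sample indexing.  The inter-trial rest is
a configurable 5 s default; onsets are
$10 + (k-1)\,(30 + 5)$ s.  The 18 s response window is timeline metadata
only and does not affect segmentation.  Segmentation of a uniformly
sampled stream is exact: a trial tensor is `optodes × 2 × round(30 fs)`
(16 × 2 × 60 at 2 Hz, 4 × 2 × 120 at 4 Hz) and concatenated trials never
share a sample.

# Classification

Trial tensors are flattened optode-major (HbO₂ block before hHb, time
fastest) to 1920 features (16-optode profile) or 960 (4-optode profile).
The session splits into phase A (trials 1–10, labeled, gathered for
training), phase B (training, no protocol time), and phase C (trials
11–20, classified one by one as each window closes, using no future
samples).

The classifier is a linear soft-margin SVM (libsvm via `e1071`,
tolerance 1e-6, no feature scaling by default).  The cost $C$ is chosen
per subject from the 8-value grid $10^{-3}..10^{4}$ by stratified 5-fold
cross-validation on the ten phase-A trials — one trial per class per
fold, fold membership assigned within class by a seeded permutation so
both classes appear in every training fold.  Ties in mean fold accuracy
resolve to the smallest $C$ (strongest regularization, deterministic).
The trained hyperplane is stored as an oriented $(w, b)$ with
$w\cdot x + b > 0 \Rightarrow$ high load; a margin of exactly zero
resolves to low.  Session metrics (accuracy, precision, recall, F1) take
high load as the positive class and are reported in percent; precision is
undefined (NA, with a warning) when no trial is predicted high.

# Synthetic sessions

The generator emulates the statistical structure of a prefrontal
working-memory session rather than its biophysics.  The evoked response
is a unit-peak single-gamma kernel
$h(t) = (t/p)^{p/s} e^{-(t-p)/s}$ (time-to-peak $p$ = 6 s, dispersion
$s$ = 1 s; < 1e-4 by 25 s, safely inside the 30 s window), scaled by a
load-dependent amplitude — defaults 0.5 µM (low) and 2.0 µM (high), a
4:1 contrast — and by a per-optode spatial gain (default: 2× on the
anterior-prefrontal ROI 2, emulating focal activation).  Δ[hHb] carries
the opposite-signed response at 1/3 amplitude.  Superimposed are white
sensor noise (sd 0.3 µM), cardiac (0.15 µM at 1.1 Hz, aliased at 2 Hz
sampling as in real recordings), respiratory (0.2 µM at 0.25 Hz), Mayer
waves (0.3 µM at 0.1 Hz) with random per-channel phases, and a random
per-channel linear drift within ±0.5 µM per session.  These levels place
single-session phase-C accuracy in the realistic 50–100% range.

What the generator does *not* model: motion and acceleration artifacts,
systemic blood-pressure confounds, scalp/skull partial-volume effects,
inter-subject anatomical variability, and nonstationary noise.  Passing
tests therefore demonstrate the pipeline's correctness and its behavior
under controlled effect sizes — not field performance on recorded data.

A subtlety worth documenting: the nuisance oscillations are coherent
across a session, and with 35 s trial spacing the 0.1 Hz Mayer wave
advances exactly 3.5 cycles per trial, so consecutive trials carry
opposite oscillation phase.  A classifier can exploit this geometry, so
chance-level and effect-size experiments must randomize the trial
sequence afresh each replicate (`effect_size_sweep(fresh_sequence =
TRUE)`, the default); holding one sequence fixed across replicates
biases agreement with that sequence's labels far from 50%.

Ground truth accompanies every simulated session: the label sequence and
the noiseless per-trial peak response per optode and chromophore.  With
noise disabled, the measured peak response equals the configured
amplitude exactly, and the optional raw-intensity encoding (inverse mBLL
around a 1000-unit baseline) round-trips through the optical front end
to better than 1e-6 µM.

# Offline statistics

* `roi_average()` — unweighted spatial mean over contiguous optode
  blocks (1–4, 5–8, 9–12, 13–16 for the 16-optode band; identity for the
  4-optode band).
* `peak_response()` — per-trial peak within 30 s post-onset minus the
  2 s pre-onset mean.  The peak is the signed deviation of largest
  magnitude, so the negative-going hHb response reports its trough
  rather than a value pinned near zero.
* `group_summary()` — mean and sample (n−1) standard deviation, the
  convention that reproduces the published per-subject table aggregates.
* `cohens_d()` — pooled-sd effect size with (n−1) weights.  From rounded
  summaries (5.33 ± 1.95 vs 8.25 ± 2.42, n = 12 each) it gives 1.333,
  matching a published 1.34 computed from unrounded data within 2%.
* `unpaired_t_test()` — classic equal-variance two-sample test by
  default (Welch optional).
* `binomial_chance_threshold()` — smallest accuracy whose exact binomial
  tail at chance level 0.5 is ≤ α; 75% for 20 trials, 90% for 10 trials
  at α = 0.05.  This is the bar against which small-sample classifier
  accuracies should be read.

# Numerical choices and degenerate inputs

* EMA recursion runs through the C-level recursive filter
  (`stats::filter`), verified against the literal recurrence to 1e-12.
* Sequence generation rejects and redraws; for the 20-trial session about
  3% of balanced permutations satisfy both constraints (≈ 33 draws on
  average, microseconds in practice), and an explicit cap turns
  pathological configurations into an error.
* Non-uniform timestamps are an error in strict mode; the online session
  runner tolerates dropped samples (gaps), skipping — with a warning —
  any trial whose window is incomplete, and excluding it from metrics.
* Zero-margin predictions resolve to low load; equal CV accuracies
  resolve to the smallest cost; both are deterministic tie-breaks.
* A singular extinction matrix, non-positive intensities, missing
  pre-trial coverage, and class-free training sets are all rejected with
  located errors rather than propagated as NaN.

# Problem sizes in the validation suite

The simulation-based checks use the 16-optode / 2 Hz profile with
20-trial sessions (1420 samples × 32 channels): 200 replicates for the
chance-level test, 200 for the strong-effect test, and 20 per point on a
five-point amplitude grid for monotonicity — enough replication that the
binomial error of a mean accuracy is about 1.1 percentage points.

# Known limitations

* Concentration values are only as interpretable as the extinction table
  and DPF supplied; comparisons across devices should use the same table.
* The MACD band edges are nominal: the 6 s/13 s windows give a broad,
  shallow band-pass (peak gain ≈ 0.33 near 0.035 Hz), not a sharp
  0.02–0.33 Hz brick wall.
* The per-subject SVM is trained on ten trials; its accuracy estimate on
  ten more has a binomial sd of ~16 percentage points.  Single-session
  accuracies should be compared against `binomial_chance_threshold()`,
  not against 50%.
* No motion-artifact handling: the package assumes the quality checks
  (`check_saturation()`) and the band-pass filter are sufficient, which
  holds for the synthetic model but not necessarily for ambulatory
  recordings.
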