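---
title: "Wavelet EMG pattern analysis of one-leg hop trials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet EMG pattern analysis of one-leg hop trials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopwave)
```

## The problem

After anterior cruciate ligament reconstruction (ACLR), patients often show
neuromuscular adaptations that conventional discrete EMG measures (onset
times, peak amplitudes, co-contraction indices) fail to detect. This package
implements a sensitivity-oriented alternative: surface EMG recorded during a
one-leg hop is decomposed into a time-frequency *intensity pattern* per
muscle, the patterns are normalized so that only their *shape* matters, and a
1-nearest-neighbor classifier with leave-one-out cross-validation (LOOCV)
asks whether patterns from two limbs or groups are distinguishable. A
binomial criterion converts classification rates into significance
statements. A companion set of tools relates clinical and functional
outcomes (thigh girth, knee laxity, hop distance, Tegner activity score) to
a summed MRI-based knee degeneration score (a WORM-type total) through
Pearson correlations and stepwise regression.

Because raw recordings from the underlying human study are not publicly
available, the package ships a synthetic cohort generator that emulates the
acquisition protocol with known ground truth, so that every stage of the
pipeline is testable end to end.

## Signal chain

### Acquisition model

Seven muscles are recorded bilaterally at 3000 Hz (GM, GL, TA, VM, RF, BF,
ST), together with vertical ground reaction force (vGRF) at 3000 Hz and
motion capture (ankle vertical velocity, knee flexion) at 125 Hz. All events
are reported as 1-based sample indices on the EMG clock; mocap sample $m$
maps to EMG sample $24(m-1)+1$ under the default rates (the general rule
uses the rounded rate ratio).

### Conditioning

EMG is conditioned in two conceptual stages: a notch comb removing 60 Hz and
every harmonic below the band edge (60, 120, ..., 660 Hz), then a 7–700 Hz
band-pass. The package realizes both as *zero-phase frequency-domain
filters*: the record is reflect-padded by one warm-up length (0.5 s), the
outer half of each pad is cosine-tapered to zero, and the transform is
multiplied by a real nonnegative gain — Gaussian notches
$1 - e^{-(f-h)^2/2\sigma^2}$ (with $\sigma$ a quarter of the nominal notch
bandwidth, default 4 Hz) times a Butterworth-magnitude band-pass
$[1+(f_{lo}/f)^{2k}]^{-1/2}[1+(f/f_{hi})^{2k}]^{-1/2}$ with $k = 8$
(order 4 edges). Real gains give exactly zero phase, so envelope peaks are
never shifted; the constant (DC) component is handled exactly by demeaning
before the transform and restoring the mean through the DC gain. The
realization is defined by measurable contracts rather than a named filter
family: $\ge$ 30 dB attenuation at each harmonic, $\le$ 1 dB loss for tones
at least one notch bandwidth away and at mid-band, $\ge$ 20 dB attenuation
at 1 Hz, zero-phase cross-correlation lag. All contracts are tested.

### The wavelet filter bank

The time-frequency decomposition uses a bank of 14 non-linearly scaled
Gaussian-like wavelets defined in the frequency domain. Central frequencies
follow

$$\mathrm{cf}(j) = \frac{1}{s}\,(j + q)^{r}, \qquad j = 0, \dots, 13,$$

with $s = 0.3$, $q = 1.45$, $r = 1.959$, giving 6.90 Hz for the first and
623.8 Hz for the last wavelet — tight spacing at low frequencies where EMG
spectra are dense, coarse at high frequencies, all inside the 7–700 Hz band.
Each wavelet's gain is

$$W_j(f) = \left(\frac{f}{\mathrm{cf}_j}\right)^{\mathrm{cf}_j s}
  \exp\!\left[\left(1 - \frac{f}{\mathrm{cf}_j}\right)\mathrm{cf}_j s\right],$$

which equals 1 at its own central frequency and whose bandwidth grows with
$\mathrm{cf}_j$ (the usual time-frequency resolution trade-off; both
properties are tested). The gain exponent
$\mathrm{cf}_j s\,[\log x + 1 - x] \le 0$ is evaluated in log space so gains
never overflow.

Per band, the *intensity* is the squared magnitude of the analytic
representation of the band-filtered signal: positive-frequency components
are doubled, negative ones zeroed, and the inverse transform's modulus is
squared. This yields a nonnegative, time-resolved, lag-free power measure —
the properties the later normalization and averaging require. Intensity
scales exactly quadratically with amplitude, and for stationary band-limited
noise its time average is proportional to signal variance (recovered within
5% on a 10 s record in the tests).

### Hop phases

The hop is segmented by four events:

* **t2 (contact)** — first vGRF sample above 50 N coming from below, after
  an unloaded interval;
* **t3 (peak force)** — maximum of the landing transient at or after t2; a
  force series that never falls after contact has no landing peak and is an
  error;
* **t1 (take-off)** — minimum ankle vertical velocity strictly before the
  mocap image of t2, mapped back to the EMG clock;
* **t0 (movement onset)** — both the rectified EMG activity (across-muscle
  mean absolute amplitude, causal 25 ms moving average) and knee flexion
  must depart their quiet-standing baselines. The EMG rule requires
  baseline mean + 3 SD (plus a 2% relative floor so an all-quiet record
  cannot trigger) to be exceeded for a sustained 25 ms run, then backtracks
  to the first sample above the statistical threshold alone; the reported
  t0 is the later of the two channel-wise onsets.

Phases are `[t0, t1)`, `[t1, t2)`, `[t2, t3]` — half-open so the frames
partition the record. Ordering is enforced on every return, with the
violated constraint named in the error. The onset constants (3 SD, 25 ms
sustain, 0.3 s baseline) are standard onset-detection conventions, exposed
as arguments; the source protocol describes onset only qualitatively.

### Normalization

Each phase is linearly resampled to 100 frames (endpoints inclusive), the
phases are concatenated (14 bands x 300 frames), and each band is
z-normalized — mean subtracted, divided by the standard deviation — *per
trial, per muscle, per band, over all 300 frames*. The alternative reading
of the normalization (across trials at each frame) would drive group means
toward zero and contradict the subsequent averaging step, so the per-trial
reading is adopted; the z-scope is recorded in configuration metadata
(`z_normalize_scope: per-trial`). A zero-variance band cannot be normalized:
it is set to zero and flagged with a warning, never silently dropped. The
composition intensity → time-warp → z-normalization is invariant to the
overall EMG gain of a trial (tested to 1e-6 under a x10 amplitude change),
which is the point: between-subject baseline intensity differences are
removed and only pattern shape remains. Min–max `[0, 1]` rescaling exists
for display export only and never feeds classification.

## Classification and significance

Patterns are vectorized row-major — 4200 features for the whole hop, 1400
for a single phase — and classified per muscle with 1-NN (Euclidean
distance; the metric is an argument) under LOOCV for three pair-wise
comparisons: control index vs control contralateral (bilateral symmetry in
controls), ACLR surgical vs ACLR contralateral (bilateral symmetry in
ACLR), and ACLR contralateral vs control index (group difference). Exact
distance ties are broken by the lowest sample index; the rule is load-bearing
for reproducibility (an alternating 4-point toy classifies 0/4 under it and
is frozen in the tests).

The cross-validation unit defaults to the **subject**: all trials of a
subject are held out together, so trials of the same person can never be
both query and reference. Trial-level LOOCV is provided as a first-class
option because the published per-trial denominators imply it, but it lets
same-subject trials leak between folds and inflates rates far above chance;
the subject-level default is the defensible choice. Conversely, subject-level
holdout carries a small conservative bias: removing a subject's trials
shrinks its own class in the reference set, so a pure-noise comparison with
33-vs-36 trials expects about 45.5% rather than 50% correct. Both effects
are visible in the package's own simulation tests and are discussed under
limitations.

A rate is significant when it *strictly exceeds* the critical classification
rate: the smallest $k/n$ whose one-sided test against chance (0.5) falls
below the Bonferroni-adjusted level $\alpha/m$. Both the exact binomial test
and the normal approximation of a proportion (no continuity correction) are
implemented, because the conventions disagree at the study's size: at
$n = 23$ and $\alpha = 0.05/3$, the normal approximation gives $k = 17$
(73.9%, $z = 2.29$, $p = 0.0109$) while the exact test gives $k = 18$. The
published threshold of 73.9% corresponds to the normal-approximation
convention, which is therefore the default; every verdict records the method
used. The published unadjusted figure of 65.2% ($=15/23$) is *not*
reproducible under any convention implemented here (the exact unadjusted
one-sided test gives 16/23 = 69.6%, the normal approximation 15.7/23), and
no function claims to reproduce it. A power utility reports the smallest
detectable true proportion for a given design alongside the threshold.

## Outcome statistics

`pearson_cor()` reports $r$ with a two-tailed t-based p-value;
`correlate_outcomes()` applies it pairwise against the degeneration score
with pairwise deletion and per-pair $n$, without multiplicity adjustment
(mirroring the source analysis). Correlations are reported as signed $r$
(and $r^2$ derivable from it) — never as a signed "$R^2$".
`stepwise_regression()` is bidirectional: forward steps add the candidate
with the smallest partial-F p-value while it is below `alpha_enter` (0.05),
backward steps remove included terms above `alpha_remove` (0.10);
`alpha_remove >= alpha_enter` guarantees termination, ties break
alphabetically, perfectly collinear candidates are rejected by name, and the
full step log is returned. The entry/removal thresholds are conventional
defaults — the source reports no values — and are arguments.

`summarize_cohort()` uses sample SDs ($n-1$) with 1-decimal reporting
columns; on the packaged 23-subject demographics table it reproduces the
published ACLR summaries (age 34.7 +/- 9.9 years, follow-up 11.9 +/- 1.3
years). The published *control* mean age (38.8) excludes the one control
recruited outside the parent study; the package computes over all 12
controls and therefore reports 37.8, which is documented rather than
special-cased.

## The synthetic cohort generator

The generator is the package's test bed: it must give every downstream
stage a ground truth, not reproduce biomechanics. Per muscle, EMG is built
as Gaussian-envelope bursts (truncated at +/- 3 SD so the pre-movement
baseline is exactly quiet) riding on a unit-RMS carrier of band-limited
noise shaped by a Gaussian spectral window (SD 35 Hz) at a muscle-specific
centroid (83–125 Hz), plus a low tonic activation with a sharp onset at t0,
60 Hz line contamination, and white noise. Burst timing follows a plausible
hop timetable (plantar flexors pushing off late in take-off, TA active in
swing, quadriceps in take-off and landing absorption, hamstrings airborne
and landing). The force channel is zero until contact, first exceeds 50 N
exactly at the constructed t2, and peaks in a sharp impact transient exactly
at t3; ankle velocity attains its pre-contact minimum exactly at the mocap
sample defining t1; knee flexion leaves its static baseline two mocap
samples before t0 so that the EMG onset is the later — hence defining —
channel.

Group differences are injected where the comparisons look for them:
quadriceps take-off bursts gain amplitude (+35% per unit effect) and fire
earlier; hamstring airborne bursts are latent, shorter and more intense with
an upward centroid shift; GM, GL and TA carry *no* group effect, providing
negative controls. The effect is expressed fully in the ACLR surgical limb
and at 90% in the contralateral limb, emulating bilateral near-symmetry
within the ACLR group alongside a clear group-vs-control difference. At
`effect_size = 0` the group label provably has no influence (same substream,
identical signals — tested). Subject random effects (amplitude x
exp(N(0, 0.15)), timing +/- 15 ms, centroid +/- 5 Hz) sit atop per-trial
jitter (x exp(N(0, 0.10)), 8 ms, 3 Hz) — chosen once as a realistic ratio of
between- to within-subject variability for surface EMG patterns. Seeding is
hierarchical: one master seed; per-trial and per-subject substreams derived
by hashing (subject, limb, trial), so any single trial regenerates
identically in isolation.

Outcome tables follow a configurable linear link: degeneration score =
intercept + slope x girth deficit + weak hop-ratio term + noise, with
defaults slope −20.8 and intercept −8.3 so regression recovery has a known
truth; scores are floored at zero (the score is a sum of nonnegative
gradings), laxity, hop ratio, Tegner, age and BMI are drawn at plausible
group-specific values.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: motor-unit physiology (recruitment,
non-stationarity within bursts, fatigue), electrode artifacts and movement
noise, realistic inter-muscle correlation structure, force-plate center of
pressure, or marker-based kinematics. The generator demonstrates that the
*pipeline* recovers known structure; it cannot validate the clinical claims.

## Numerical choices and problem sizes

* Frequency-domain filtering uses transform lengths padded to the next
  2-3-5-smooth integer; reflect padding is 0.5 s for conditioning and 0.3 s
  for the wavelet stage (longer than the slowest wavelet's support).
* Time normalization interpolates linearly on the normalized phase axis,
  endpoints inclusive; a phase of exactly 100 samples reproduces its values
  verbatim.
* Event detectors operate on raw indices with no smoothing except the
  documented 25 ms onset window and return errors, never guesses, for
  degenerate inputs (no crossing, flat force, empty pre-contact window,
  unreachable threshold).
* The simulation test batteries use the study's sizes — 11 + 12 subjects,
  two limbs, three trials — with 20 replicates for classification
  properties and 200 replicates for regression recovery; tiny 2 + 2 cohorts
  back the fast unit tests.

## Known limitations

* **Null calibration is approximately, not exactly, binomial.** Under
  subject-level LOOCV at the study's size, per-muscle null rates center
  near 47% (class shrinkage, see above) with dispersion about 1.2x binomial
  (subject clustering correlates the three trials of a limb). The central
  95% binomial band around 50% captures ~90% of null rates at this size
  rather than 95%; the discrepancy vanishes as cohorts grow. This is a
  property of leakage-free LOOCV itself, not of the implementation, and the
  package's calibration tests document it.
* The exact exclusion rule behind the published per-comparison denominators
  (69/62/63 where full cohorts give 72/66/69) is unknown;
  `missing_trial_rate` emulates per-trial dropout generically.
* Whether the original analysis z-normalized before or after time-warping,
  and its LOOCV unit and distance metric, are unstated; this package warps
  first, defaults to subject-level folds and Euclidean distance, and exposes
  all three as configuration.
* The stepwise variant (forward/backward/bidirectional) and its thresholds
  are unstated in the source; bidirectional with 0.05/0.10 is implemented
  and logged per step.
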