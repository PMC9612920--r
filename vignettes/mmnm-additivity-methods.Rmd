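---
title: "Models and methods: additivity of magnetic mismatch responses"
author: "MMNmAdditivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: additivity of magnetic mismatch responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MMNmAdditivity)
```

## The scientific question

The mismatch negativity and its magnetic counterpart (MMNm) index the
brain's detection of an unexpected sound in a sequence of expected ones.
When a deviant differs from the standard in two or three acoustic features
at once — here fundamental frequency (F, −35 cents), intensity (I, −12 dB)
and perceived location (L, a 200 µs inter-aural delay) — an *additive
model* predicts that the combined response equals the sum of the
single-feature mismatch responses. Departures from additivity
(*subadditivity*: the empirical response falls short of the modeled sum)
are read as evidence that the features are processed by shared, integrated
neural resources rather than independent ones. The package implements the
complete analysis chain for this question — paradigm construction,
sensor-space simulation, preprocessing, mismatch-wave construction, and
nonparametric cluster statistics for the additivity-by-expertise
interaction — and validates it on synthetic cohorts whose ground truth is
known.

## Ground-truth model

Every simulated condition is a sum of separable components over a
spherical planar-gradiometer array. For deviant type $d$ with constituent
features $C(d) \subseteq \{F, I, L\}$ and group $g$:

$$E_d(c, t) = S(c, t) + \bigl(1 - \kappa_{g,d}\bigr)
  \sum_{f \in C(d)} \beta_f\, b_f(c)\, w_f(t),$$

where $S$ is the standard evoked response (latency 100 ms), each mismatch
component has a Gaussian waveform $w_f$ peaking at 156 ms, a nonnegative
spatial profile $b_f$ over bilateral temporal hotspot regions, amplitude
$\beta_f$, and $\kappa \in [0, 1]$ is the ground-truth *subadditivity
coefficient* — zero for standards and single deviants, and by default
positive only in the expert group and only for frequency-containing
combinations, mirroring a feature-selective integration effect. Trials add
a subject-level log-normal gain (CV 0.2) and stationary Gaussian noise with
spatial covariance $\exp(-d/\lambda)$ across sites ($\lambda$ = 6 cm) and
AR(1) structure over time ($\phi = 0.7$ at 250 Hz).

The pair-level field magnitude is projected onto the two orthogonal
gradiometers of a site as $b\cos\psi$ and $b\sin\psi$ with a fixed
per-site phase $\psi$, so root-mean-square combination recovers the
magnitude exactly in the noise-free case.

**Amplitudes and noise are not published values.** No evoked amplitudes in
fT/cm are reported for the original recordings, so $\beta_f = 10$,
standard amplitude 15, and noise SD 33.3 (single-trial SNR $\approx 0.3$
at the mismatch peak) are this package's own defaults, chosen so that
presence tests are near ceiling at the full design size while the
interaction test has moderate power — the regime in which the validation
experiments are informative.

### Why the additive identity is exact here

Planar combination rectifies ($\mathrm{RMS} \ge 0$), and rectification
does not commute with addition, so sum-of-singles equality for a
double-deviant response is *not* automatic on the combined scale. Two
deliberate modeling choices make it exact: (i) the three feature
components share one latency and width (their topography centers and
amplitudes differ), so their waveforms never have opposite signs at the
same sample; and (ii) the standard-response topography and the mismatch
topographies have compactly supported, spatially disjoint sensor
footprints (cosine-tapered profiles that reach exactly zero). At every
channel the rectified combination then acts on same-sign quantities, the
absolute values distribute over the sum, and the empirical and modeled
mismatch waves agree sample-for-sample at $\kappa = 0$ — through the full
preprocessing chain, since all remaining stages are linear. The test suite
asserts this at $< 10^{-8}$. Overlapping sources would make the identity
approximate; real cortical geometry certainly overlaps, which is one
reason the package's passing tests bound implementation correctness, not
physiological realism.

## Paradigm construction

The complex musical multi-feature paradigm arpeggiates an Alberti-bass
pattern (lowest–highest–middle–highest, rendered as major-triad semitone
offsets 0–7–4–7 from the root) at a 205 ms SOA. A block holds three
iterations of the 12 chromatic roots from A#2 (116.54 Hz) to A3
(220.00 Hz); at each root the seven deviant types occur once in seeded
pseudo-random order, each deviant pattern preceded by three standard
patterns, with the deviant always on pattern position 3. This gives
exactly 4032 tones (826.56 s ≈ 13 min 47 s) and 36 deviants per type per
block — 144 over four blocks. The simple control paradigm presents single
tones at a 400 ms SOA, four iterations of the 12 roots with the seven
deviants in permuted order, each preceded by 3–5 standards drawn
uniformly; 48 deviants per type per block, 144 over three blocks, expected
duration 672 s ≈ 11 min.

Decisions taken where the design was open:

* *Analysis standards in the complex paradigm.* Only the third standard
  after each deviant enters the standard average. A pattern position is
  not dictated for it, so the package epochs the position-3 tone (the
  position deviants occupy) of the third standard pattern — matched
  acoustic and positional context between conditions.
* *"Pseudo-random"* is read minimally: seeded uniform shuffles, with the
  single constraint that the same pitch level never repeats across slot
  boundaries.
* *Block edges.* A deviant with fewer than three trailing standards
  contributes no standard trial; blocks are separated by breaks, so no
  borrowing across blocks.
* Scientific pitch notation with A4 = MIDI 69 = 440 Hz.

## Preprocessing

The chain is fixed: jump rejection → band-pass → planar combination →
baseline → averaging.

* *SQUID-jump rejection.* The criterion named in the field is only "a
  z-value cutoff of 30"; the package defines the z-score on absolute first
  differences of each trial, standardized per channel against the pooled
  mean/SD over all trials and samples — sensitive to steps, insensitive to
  slow evoked components. It is validated against injected synthetic
  jumps, where it removes all and only the contaminated trials; a
  median-filtered-derivative variant would behave similarly for the step
  artifacts modeled here.
* *Band-pass.* Zero-phase two-pass Butterworth, order 4 per pass, 1–40 Hz,
  after mirror-padding each epoch to 3 s. The two-pass response is applied
  as the squared magnitude response $|H(\omega)|^2$ of the bilinear-design
  filter in the frequency domain of the padded series: one FFT per batch
  of series rather than one IIR recursion per series, which is what makes
  filtering $10^5$ trial–channel series per cohort affordable. On a single
  series the result matches `signal::filtfilt` on the same padded data to
  well under 1% RMS; DC is removed exactly (the design has zeros at DC).
* *Planar combination.* "Root-mean-square of the two gradients" is taken
  literally: $\sqrt{(a^2+b^2)/2}$. The common vector-magnitude convention
  $\sqrt{a^2+b^2}$ is a flag; all inferential results are invariant to the
  global $\sqrt 2$.
* *Baseline.* Mean over −50–0 ms, applied after combination, hence to the
  rectified signal — as standard toolboxes do when configured this way.
  Baseline correction is linear and idempotent.
* All mismatch subtraction happens **after** combination; a regression
  test guards this order because RMS is the one nonlinear stage.

## Cluster-based permutation statistics

Samplewise pooled-variance $t$ maps over the selected sensors × 100–300 ms
window are thresholded at the two-tailed critical value at $\alpha = .05$
with the design's degrees of freedom. Supra-threshold samples of the same
sign connect if they are neighbors in time (same pair, adjacent samples)
and/or space (same sample, pairs within the distance threshold). The
"minimum two neighbor sensors" admissibility rule is interpreted as a
cluster-level filter — an assembly must contain at least two mutually
neighboring pairs — rather than a per-sample neighbor count; with
spatial connection possible only through neighboring pairs the two
readings coincide for connected components here. The cluster statistic is
the per-sign maxsum; two-sidedness is handled by sign-separated null
distributions, each compared at half the overall alpha (0.025, or 0.00625
after Bonferroni correction over the four modeled-vs-empirical
comparisons). Monte Carlo p-values use the $(b+1)/(m+1)$ estimator, which
can never be zero and is valid by construction; when the requested number
of permutations reaches the number of distinct relabelings the test
switches to exhaustive enumeration with exact p-values (all group
partitions, or all $2^n$ sign flips for the paired design). Cluster
formation is cross-checked against an independent graph-components oracle
on random grids, and Monte Carlo p-values against exhaustive enumeration
on small fixtures.

The sensor neighborhood derives from linear inter-pair distance; the
default threshold is the smallest distance giving a mean of at least three
neighbors per selected pair, and is recorded in the result. Peak sensors
are chosen per hemisphere from the grand-average mismatch wave pooled over
all subjects, conditions and paradigms (the combined signal is
nonnegative, so no polarity handling); each peak contributes its eight
nearest same-hemisphere pairs, 2 × 9 = 18 in total, with ties broken by
the lowest pair id and no crossing of the midline.

## Validation experiments and problem sizes

`runStudy()` exercises the full trial-level chain (paradigm → simulation →
jump injection/rejection → preprocessing → mismatch waves → pooled sensor
selection → all presence/ordering/interaction/simple-effect tests) under a
single master seed from which every stage seed derives; identical seeds
give identical reports. Presets scale the cohort: the `full` design (25
subjects per group, 144 trials per deviant, 10,000 permutations) and
reduced `scaled`/`tiny` presets whose sizes (8/36/1000 and 4/12/250) keep
an end-to-end run in the tens of seconds.

The statistical validation experiments — type-I error, power, and
recovery of $\kappa$ — simulate cohorts at the *subject-evoked level*:
each condition's trial average is drawn directly with noise scaled by
$1/\sqrt{n}$, exploiting the linearity of averaging. Band-pass filtering
is omitted in this shortcut: the generated components are already inside
the passband, and the filter, being linear and common to all conditions
and groups, cannot affect exchangeability under permutation. Jump
artifacts are likewise exercised only in the trial-level chain. The
shipped problem sizes are 200 null replicates at $n = 10 + 10$ with 500
permutations for the type-I experiment (the observed false-positive rate
must bracket the nominal 0.05), 40 replicates per point of a
$\kappa \in \{0, 0.2, 0.5\}$ grid for power (common random numbers across
the grid make the curves monotone up to Monte Carlo error; the IL
combination keeps $\kappa = 0$ under the feature-selective default and
stays at the null rate), and 20 replicates at $n = 25$ for recovery.

## Estimating the subadditivity coefficient

The estimator is defined by this package (nothing equivalent is reported
for the original data):

$$\hat\kappa = 1 -
  \frac{\sum_s \langle \mathrm{emp}^B_s,\, T \rangle}
       {\sum_s \langle \mathrm{mod}^B_s,\, T \rangle},
\qquad T = \frac{1}{n}\sum_s \mathrm{mod}^A_s,$$

with inner products over the selected pairs × window, trials split into
independent halves A and B (standard trials split too), and maps taken on
the **raw pair channels**, where the mismatch subtraction is linear and
the empirical signal is exactly $(1-\kappa)$ times the modeled one.

Three simpler estimators fail at the default SNR and motivated this
design. The naive regression $1 - \langle \mathrm{emp}, \mathrm{mod}
\rangle / \langle \mathrm{mod}, \mathrm{mod} \rangle$ is attenuation-biased
because the modeled regressor is noisy and shares the standard average
with the empirical wave. Moving to split halves removes the bias in
expectation but, per subject, noise×noise cross-products summed over
roughly 1800 correlated map cells dominate both inner products. And any
estimator on the *combined* scale inherits the rectified noise floor,
which distorts low-SNR cells nonlinearly. The cohort-template form solves
both residual problems: the reference $T$ is the only repeated factor,
its noise shrinks with the number of subjects, and it acts as a matched
filter concentrated on the mismatch signal.

Two properties make the remaining analysis clean. First, conditional on
$T$ — which is independent of every B-half map — the per-subject inner
products are independent across subjects and their expected ratio is
exactly $1 - \kappa$ for *any* realization of the template. Second, the
ratio of random sums still carries a finite-sample $O(1/n)$ bias
(measurably so at 144 trials), which `kappaRecovery()` removes with a
leave-one-subject-out jackknife over the B-half sums, the template held
fixed. At the default SNR with 25 subjects the recovery experiment then
measures $|\mathrm{bias}| < 0.05$ at 144 trials and RMSE falling from
roughly 0.1 at 144 trials to 0.05–0.08 at 288; on noise-free data the
estimator is exact up to machine precision. At very low trial counts
(72, i.e. 36 per half) the denominator sum can come close to zero in an
occasional replicate and the estimate is heavy-tailed — the RMSE there is
dominated by rare outliers, and estimates below the study's actual count
of 144 trials per deviant should be treated with caution.

## What the simulation does and does not capture

The generator reproduces the design's structure (conditions, trial
counts, epoch timing, planar-gradiometer geometry, analysis-standard
selection), realistic spatiotemporal noise correlation, inter-subject
amplitude variability, and step artifacts for the rejection rule. It does
**not** simulate 1/f or physiological noise, eye/heart artifacts,
head movement, source-space geometry, overlapping standard/mismatch
sources, latency jitter between subjects, or secondary mismatch peaks in
the 200–300 ms range (a second component can be added through the
configuration but is off by default). Passing tests therefore demonstrate
that the pipeline's arithmetic, statistics and bookkeeping are correct
under a known ground truth — not that the effect sizes or p-values of any
real recording would be reproduced.

## Numerical choices and degenerate inputs

Zero-variance samples give $t = 0$ rather than NaN. Channels with zero
pooled difference-SD are ignored by the jump detector. Ties in peak
selection and neighbor ranking break on the lowest pair id, making
selection deterministic. Seeds are dispensed from a master seed through a
fixed-order pool, so adding replicates never reshuffles earlier stages;
the caller's RNG state is always restored. Epoch windows must give an
integer sample count (126 samples at 250 Hz for −100–400 ms). Exhaustive
enumeration is capped at 12 subjects (independent) and 14 (dependent);
beyond that the Monte Carlo path with the validity-guaranteeing estimator
is used. All file outputs are plain text (TSV event logs and layouts, CSV
report tables, JSON provenance).
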