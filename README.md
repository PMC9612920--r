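# MMNmAdditivity

Additivity analysis of magnetic mismatch responses (MMNm) in
multi-feature auditory oddball paradigms, for researchers in auditory
neurophysiology and for methodologists who want a fully synthetic,
ground-truth-controlled testbed for spatiotemporal cluster statistics.

## The question and the model

A deviant tone violating a regularity elicits a mismatch response peaking
~150–250 ms after deviance onset. For a deviant that changes several
acoustic features at once — frequency (F, −35 cents), intensity (I,
−12 dB), perceived location (L, 200 µs inter-aural delay) — the *additive
model* predicts

&nbsp;&nbsp;&nbsp;&nbsp;MMNm(FI) = MMNm(F) + MMNm(I),

and likewise for IL, LF and FIL. The *modeled* MMNm is this sum of
empirical single-feature difference waves; *subadditivity* (empirical <
modeled) indicates integrated processing of the features. Whether
subadditivity differs between expertise groups is an interaction, tested
nonparametrically: pooled-variance t maps over selected sensors × 100–300
ms are thresholded at α = .05, supra-threshold samples are clustered over
space–time (neighbors by linear sensor distance; clusters must span at
least two neighboring sensors), each cluster is summarized by its summed
t (maxsum), and the observed per-sign maximum is compared against a
permutation null (group-label exchange, or sign flips for paired
designs), with Bonferroni-corrected per-tail α = 0.025/4 = 0.00625 for
the four additivity comparisons.

The package provides, as testable components: the complex (Alberti-bass,
SOA 205 ms) and simple control (SOA 400 ms) paradigm generators; a
planar-gradiometer simulator with a known subadditivity coefficient κ
(the fractional shrinkage of the summed mismatch components); the
preprocessing chain (SQUID-jump rejection at z = 30, zero-phase 1–40 Hz
Butterworth band-pass with 3 s padding, planar RMS combination, 50 ms
baseline); mismatch-wave construction and 2 × 9 peak-sensor selection;
the cluster permutation engine with an exhaustive small-sample oracle;
and study-level experiments (type-I error, power, κ recovery).

## Worked example

```r
library(MMNmAdditivity)

## 1. Paradigm: one complex block
block <- markAnalysisStandards(generateComplexBlock("M1", seed = 1))
block
#> BlockSequence 'M1' (complex paradigm): 4032 tones, 252 deviants, 826.56 s
head(paradigmTrialTable(list(block)), 4)
#>   paradigm condition n_deviants n_analysis_standards total_duration_s
#> 1  complex       STD          0                  251           826.56
#> 2  complex         F         36                    0           826.56
#> 3  complex         I         36                    0           826.56
#> 4  complex         L         36                    0           826.56

## 2. Synthetic cohort with known subadditivity: kappa = 0.5 for
##    frequency-containing combinations in musicians, 0 elsewhere
layout <- makeLayout(51, seed = 1)
cfg <- simulationConfig(
  kappa = list(musician    = c(FI = 0.5, IL = 0, LF = 0.5, FIL = 0.5),
               nonmusician = c(FI = 0,   IL = 0, LF = 0,   FIL = 0)),
  noise = list(lambda = 0.06, phi = 0.7, sigma = 10, subjectCV = 0.1))

## 3. One subject through the trial-level chain
epochs <- simulateSubject(cfg, layout, "musician", "s01", seed = 2,
                          trialsPerDeviant = 48)
pp <- preprocessPipeline(epochs)
pp$report
#> RejectionReport: 384/384 trials retained (100.0%)

## 4. Empirical and modeled mismatch waves for 8 + 8 subjects
waves <- list()
for (group in c("musician", "nonmusician")) for (s in 1:8) {
  ev <- simulateSubjectEvoked(cfg, layout, group, paste0(group, s),
                              seed = 100 + s + 50 * (group == "musician"),
                              trialsPerDeviant = 144,
                              conditions = c("STD", "F", "I", "FI"))
  ev <- lapply(ev, function(e) baselineCorrect(combinePlanar(e)))
  waves <- c(waves,
             list(empiricalMMNm(ev$FI, ev$STD),
                  modeledMMNm(list(empiricalMMNm(ev$F, ev$STD),
                                   empiricalMMNm(ev$I, ev$STD)))))
}

## 5. Peak sensors from the grand-average empirical mismatch wave
empirical <- Filter(function(w) w@kind == "empirical", waves)
grand <- grandAverage(empirical)
sel <- selectPeakSensors(grand, layout)
sel
#> SensorSelection: 2 x 9 pairs, peaks L=17 R=21, window 0.1-0.3 s
peakLatency(grand, sel, layout)
#> [1] 0.156

## 6. Additivity-by-expertise interaction at the corrected alpha
res <- interactionTest(waves, "FI", layout, sel,
                       testSpec("independent", nPerm = 1000,
                                alphaInference = bonferroniAlpha(), seed = 3),
                       groups = c("musician", "nonmusician"))
res
#> ClusterResult (independent design, 1000 permutations, seed 3)
#>  sign nCells        sumT           p
#>    -1     41 -241.380899 0.000999001
#>    -1     48 -227.939203 0.000999001
#>    -1      2   -4.658436 0.688311688
#>    -1      3   -7.642466 0.513486513
```

Reading the output: the block generator reproduces the design arithmetic
(4032 tones in 826.56 s, 36 deviants per type, one analysis standard per
deviant except the block-final one). The grand-average mismatch peaks at
156 ms, where the simulator places the components. The interaction test
finds two large negative clusters with Monte Carlo p ≈ 0.001 — below the
corrected α = 0.00625 — i.e. the empirical FI response falls short of the
modeled sum *more* in the group whose κ is 0.5, exactly the planted
effect; the two tiny clusters are noise and are correctly not
significant.

`runStudy(studyConfig(masterSeed, preset))` chains everything —
paradigms, both cohorts, preprocessing, sensor selection, and all
presence/ordering/interaction/simple-effect tests — into a seeded,
byte-reproducible report; `type1Experiment()`, `powerExperiment()` and
`kappaRecovery()` validate the statistics against the simulator's ground
truth. See the vignette in `vignettes/` for the model, the design
decisions and the estimator of κ.

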