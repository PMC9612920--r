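## Shared fixture: zero-noise combined evokeds for one subject.
mmnFixture <- function(kappaMus = ZERO_KAPPA, nPairs = 30, seed = 4) {
  lay <- makeLayout(nPairs, seed = seed)
  cfg <- zeroNoiseConfig(kappaMus)
  ev <- simulateSubjectEvoked(cfg, lay, "musician", "s1", 1,
                              trialsPerDeviant = 8)
  list(lay = lay, cfg = cfg,
       ev = lapply(ev, function(e) baselineCorrect(combinePlanar(e))))
}

test_that("empirical mismatch waves are deviant-minus-standard differences", {
  fx <- mmnFixture()
  w <- empiricalMMNm(fx$ev$F, fx$ev$STD)
  expect_s4_class(w, "MMNmWave")
  expect_equal(w@kind, "empirical")
  expect_equal(waveData(w), waveData(fx$ev$F) - waveData(fx$ev$STD))
  ## deviant equal to standard gives an all-zero wave
  stdCopy <- fx$ev$STD
  stdCopy@condition <- "F"
  expect_equal(max(abs(waveData(empiricalMMNm(stdCopy, fx$ev$STD)))), 0)
  ## peak equals the component amplitude times topography on the RMS scale
  tot <- MMNmAdditivity:::.pairSignal("F", "musician", fx$cfg, fx$lay) -
    MMNmAdditivity:::.pairSignal("STD", "musician", fx$cfg, fx$lay)
  expect_equal(max(waveData(w)), max(tot) / sqrt(2), tolerance = 1e-6)
  expect_error(empiricalMMNm(fx$ev$STD, fx$ev$STD), "deviant")
  expect_error(empiricalMMNm(fx$ev$F, fx$ev$I), "standard")
})

test_that("modeled waves sum the constituent single-deviant waves", {
  fx <- mmnFixture()
  empF <- empiricalMMNm(fx$ev$F, fx$ev$STD)
  empI <- empiricalMMNm(fx$ev$I, fx$ev$STD)
  empL <- empiricalMMNm(fx$ev$L, fx$ev$STD)
  modFI <- modeledMMNm(list(empF, empI))
  expect_equal(modFI@deviantType, "FI")
  expect_equal(modFI@kind, "modeled")
  expect_equal(waveData(modFI), waveData(empF) + waveData(empI))
  expect_equal(modeledMMNm(list(empL, empF))@deviantType, "LF")
  expect_equal(modeledMMNm(list(empF, empI, empL))@deviantType, "FIL")
  ## summation order is irrelevant
  expect_equal(waveData(modeledMMNm(list(empI, empF))), waveData(modFI))
  ## adding an all-zero wave is the identity
  zero <- empF; zero@data[] <- 0; zero@deviantType <- "I"
  expect_equal(waveData(modeledMMNm(list(empF, zero))), waveData(empF))
  expect_error(modeledMMNm(list(empF, empF)), "distinct")
  expect_error(modeledMMNm(list(empF, modFI)), "single|distinct")
})

test_that("additivity differences capture the ground-truth shrinkage", {
  fx0 <- mmnFixture()
  mk <- function(fx, dv) {
    singles <- lapply(deviantConstituents(dv), function(f)
      empiricalMMNm(fx$ev[[f]], fx$ev$STD))
    list(emp = empiricalMMNm(fx$ev[[dv]], fx$ev$STD),
         mod = modeledMMNm(singles))
  }
  w0 <- mk(fx0, "FI")
  expect_equal(max(abs(additivityDifference(w0$emp, w0$mod))), 0,
               tolerance = 1e-10)
  ## kappa = 0.3: difference is -0.3 x modeled at the peak
  fx3 <- mmnFixture(c(FI = 0.3, IL = 0, LF = 0, FIL = 0.3))
  w3 <- mk(fx3, "FI")
  d <- additivityDifference(w3$emp, w3$mod)
  i <- which.max(waveData(w3$mod))
  expect_equal(d[i] / waveData(w3$mod)[i], -0.3, tolerance = 0.02)
  ## antisymmetry under argument swap
  expect_equal(additivityDifference(w3$mod, w3$emp), -d)
  expect_error(additivityDifference(w3$emp, mk(fx3, "IL")$mod), "types")
})

test_that("grand averaging is an unweighted mean and commutes with
           differencing", {
  fx <- mmnFixture()
  empF <- empiricalMMNm(fx$ev$F, fx$ev$STD)
  neg <- empF; neg@data <- -neg@data
  expect_equal(waveData(grandAverage(list(empF))), waveData(empF))
  expect_equal(max(abs(waveData(grandAverage(list(empF, neg))))), 0)
  set.seed(9)
  waves <- lapply(1:5, function(i) {
    w <- empF; w@data <- matrix(rnorm(length(w@data)), nrow(w@data)); w
  })
  oracle <- waves[[1]]@data * 0
  for (w in waves) oracle <- oracle + waveData(w)
  expect_equal(waveData(grandAverage(waves)), oracle / 5)
  ## mean of differences equals difference of means
  mods <- lapply(1:5, function(i) {
    w <- waves[[i]]; w@kind <- "modeled"; w@deviantType <- "FI"
    w@data <- matrix(rnorm(length(w@data)), nrow(w@data)); w
  })
  emps <- lapply(waves, function(w) { w@deviantType <- "FI"; w })
  meanOfDiff <- Reduce(`+`, Map(additivityDifference, emps, mods)) / 5
  diffOfMean <- waveData(grandAverage(emps)) - waveData(grandAverage(mods))
  expect_equal(meanOfDiff, diffOfMean, tolerance = 1e-12)
})

test_that("peak-sensor selection finds planted hotspots deterministically", {
  lay <- makeLayout(51, seed = 1)
  times <- MMNmAdditivity:::timeAxis(250)
  mkWave <- function(vals) {
    m <- matrix(0, 51, 126, dimnames = list(lay@pairs$name, NULL))
    widx <- MMNmAdditivity:::windowIndices(times, c(0.1, 0.3))
    for (p in names(vals)) m[p, widx[10]] <- vals[[p]]
    colnames(m) <- times
    m
  }
  left <- lay@pairs$pair_id[lay@pairs$hemisphere == "left"]
  right <- lay@pairs$pair_id[lay@pairs$hemisphere == "right"]
  vals <- stats::setNames(c(5, 7), lay@pairs$name[c(left[3], right[2])])
  sel <- selectPeakSensors(mkWave(vals), lay)
  expect_equal(unname(sel@peakPairs["left"]), left[3])
  expect_equal(unname(sel@peakPairs["right"]), right[2])
  expect_length(selectedPairs(sel), 18)
  expect_length(unique(selectedPairs(sel)), 18)
  ## ties broken by the lowest pair id
  tieVals <- stats::setNames(c(3, 3, 1),
    lay@pairs$name[c(left[5], left[2], right[1])])
  selTie <- selectPeakSensors(mkWave(tieVals), lay)
  expect_equal(unname(selTie@peakPairs["left"]), min(left[c(2, 5)]))
  ## too few pairs in a hemisphere
  expect_error(selectPeakSensors(mkWave(vals)[1:51, ], makeLayout(12, 1)),
               "fewer than 9|missing")
})

test_that("selection is stable under moderate channel-independent noise", {
  lay <- makeLayout(51, seed = 1)
  cfg <- defaultConfig()
  sel0 <- MMNmAdditivity:::.noiselessSelection(cfg, lay)
  times <- MMNmAdditivity:::timeAxis(250)
  std <- MMNmAdditivity:::.combineMatrix(
    trueEvoked("STD", "nonmusician", cfg, lay), lay)
  grand <- Reduce(`+`, lapply(deviantTypes(), function(dv)
    MMNmAdditivity:::.combineMatrix(
      trueEvoked(dv, "nonmusician", cfg, lay), lay) - std)) / 7
  colnames(grand) <- times
  pk <- max(grand)
  set.seed(11)
  for (i in 1:50) {
    noisy <- grand + matrix(rnorm(length(grand), sd = 0.1 * pk),
                            nrow(grand))
    colnames(noisy) <- times
    sel <- selectPeakSensors(noisy, lay)
    expect_equal(sel@peakPairs, sel0@peakPairs)
  }
})

test_that("peak latency sits at the component latency and scales invariantly", {
  lay <- makeLayout(51, seed = 1)
  cfg <- defaultConfig()
  sel <- MMNmAdditivity:::.noiselessSelection(cfg, lay)
  std <- MMNmAdditivity:::.combineMatrix(
    trueEvoked("STD", "nonmusician", cfg, lay), lay)
  grand <- MMNmAdditivity:::.combineMatrix(
    trueEvoked("FIL", "nonmusician", cfg, lay), lay) - std
  gw <- methods::new("MMNmWave", data = grand, deviantType = "FIL",
                     kind = "empirical", nTrialsDeviant = 1,
                     nTrialsStandard = 1, channelNames = lay@pairs$name,
                     fsHz = 250, t0S = -0.1, subjectId = "s", group = "g",
                     paradigm = "none")
  expect_equal(peakLatency(gw, sel, lay), 0.156, tolerance = 0.004)
  g2 <- gw; g2@data <- 3.7 * g2@data
  expect_equal(peakLatency(g2, sel, lay), peakLatency(gw, sel, lay))
  ## monotone ramp peaks at the right window edge
  ramp <- gw; ramp@data <- matrix(rep(seq_len(126), each = 51), 51)
  expect_equal(peakLatency(ramp, sel, lay), 0.300, tolerance = 1e-9)
})
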