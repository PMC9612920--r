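test_that("jump rejection removes exactly the contaminated trials", {
  lay <- makeLayout(20, seed = 1)
  cfg <- defaultConfig()
  ep <- simulateSubject(cfg, lay, "musician", "s1", 11,
                        trialsPerDeviant = 20, conditions = c("STD", "F"))
  clean <- rejectJumps(ep)
  expect_equal(clean$report@retainedFraction, 1)

  epj <- injectJumps(ep, 0.1, cfg$artifact$amplitude, 21)
  rj <- rejectJumps(epj)
  expect_setequal(rj$report@rejected, epj@misc$jumpTrials)
  expect_equal(rj$report@retainedFraction,
               1 - length(epj@misc$jumpTrials) / 40)

  none <- rejectJumps(epj, zCutoff = Inf)
  expect_equal(none$report@nRejected, 0)
  expect_error(rejectJumps(epj, zCutoff = 1e-4), "review")
})

test_that("band-pass matches its design response and removes DC", {
  fs <- 250
  t <- MMNmAdditivity:::timeAxis(fs)
  dc <- bandpass(matrix(5, 1, length(t)), fsHz = fs)
  expect_lt(max(abs(dc)) / 5, 1e-6)

  g10 <- designGain2(10)
  expect_gte(g10, 0.95); expect_lte(g10, 1)
  y10 <- as.vector(bandpass(matrix(sin(2 * pi * 10 * t), 1), fsHz = fs))
  expect_equal(sineAmplitude(y10, 10, t, 20:107), g10, tolerance = 0.01)

  g60 <- designGain2(60)
  expect_lt(g60, 0.1)
  y60 <- as.vector(bandpass(matrix(sin(2 * pi * 60 * t), 1), fsHz = fs))
  expect_lt(sineAmplitude(y60, 60, t, 20:107), 0.1)

  ## agrees with the time-domain forward-backward realization
  set.seed(4)
  x <- rnorm(length(t))
  idx <- MMNmAdditivity:::.mirrorIndices(length(t), 750)
  bf <- signal::butter(4, c(1, 40) / (fs / 2), type = "pass")
  ref <- signal::filtfilt(bf, x[idx])[(750 - length(t)) %/% 2 +
                                        seq_along(t)]
  mine <- as.vector(bandpass(matrix(x, 1), fsHz = fs))
  expect_lt(sqrt(mean((mine - ref)^2)) / stats::sd(ref), 0.01)

  ## linearity
  a <- matrix(rnorm(2 * 126), 2)
  b <- matrix(rnorm(2 * 126), 2)
  expect_equal(bandpass(a + b, fsHz = fs),
               bandpass(a, fsHz = fs) + bandpass(b, fsHz = fs),
               tolerance = 1e-10)
  expect_error(bandpass(a, lowHz = 50, highHz = 40, fsHz = fs), "below")
  expect_error(bandpass(a, highHz = 200, fsHz = fs), "Nyquist")
})

test_that("planar combination equals the element-wise RMS oracle", {
  mk <- function(dat) {
    methods::new("EpochSet", data = dat,
                 channelNames = c("P001a", "P001b", "P002a", "P002b"),
                 fsHz = 250, t0S = -0.1,
                 condition = rep("STD", dim(dat)[1]),
                 analysisStandard = rep(TRUE, dim(dat)[1]),
                 subjectId = "s", group = "g", paradigm = "none",
                 combined = FALSE, misc = list())
  }
  dat <- array(0, c(1, 4, 3))
  dat[1, 1, ] <- 3; dat[1, 2, ] <- 4
  out <- combinePlanar(mk(dat))
  expect_equal(out@data[1, 1, ], rep(sqrt(12.5), 3))
  expect_equal(out@data[1, 2, ], rep(0, 3))
  expect_equal(channelIds(out), c("P001", "P002"))

  set.seed(2)
  dat <- array(rnorm(5 * 4 * 6), c(5, 4, 6))
  out <- combinePlanar(mk(dat), "sum")
  oracle <- array(0, c(5, 2, 6))
  for (tr in 1:5) for (p in 1:2) for (s in 1:6)
    oracle[tr, p, s] <- sqrt(dat[tr, 2 * p - 1, s]^2 + dat[tr, 2 * p, s]^2)
  expect_equal(out@data, oracle)
  expect_true(all(out@data >= 0))
  expect_equal(combinePlanar(mk(dat), "mean")@data, oracle / sqrt(2))

  bad <- mk(dat)
  bad@channelNames <- c("P001a", "P001b", "P002a", "P003b")
  expect_error(combinePlanar(bad), "P002|P003")
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  ev <- methods::new("Evoked", data = matrix(7, 3, 126), condition = "STD",
                     nTrials = 1, channelNames = paste0("P", 1:3),
                     fsHz = 250, t0S = -0.1, subjectId = "s", group = "g",
                     paradigm = "none", combined = TRUE)
  expect_equal(waveData(baselineCorrect(ev)), matrix(0, 3, 126))
  set.seed(3)
  ev@data <- matrix(rnorm(3 * 126, mean = 2), 3)
  bc <- baselineCorrect(ev)
  idx <- MMNmAdditivity:::windowIndices(timePoints(ev), c(-0.05, 0))
  expect_equal(rowMeans(waveData(bc)[, idx]), rep(0, 3), tolerance = 1e-12)
  expect_equal(waveData(baselineCorrect(bc)), waveData(bc),
               tolerance = 1e-12)
  expect_error(baselineCorrect(ev, c(9, 10)), "no samples")
})

test_that("condition averages behave like means and respect the
           analysis-standard restriction", {
  lay <- makeLayout(12, seed = 1)
  cfg0 <- zeroNoiseConfig()
  ep <- simulateSubject(cfg0, lay, "musician", "s1", 5,
                        trialsPerDeviant = 9, conditions = c("STD", "F"))
  av <- averageCondition(ep, "F")
  expect_equal(unname(waveData(av)), unname(ep@data[which(ep@condition == "F")[1], , ]))
  expect_equal(av@nTrials, 9)

  ## only flagged standards enter the standard average
  ep@analysisStandard[which(ep@condition == "STD")[1:4]] <- FALSE
  expect_equal(averageCondition(ep, "STD")@nTrials, 5)
  expect_error(averageCondition(ep, "IL"), "no trials")

  ## evoked RMS of pure noise shrinks as sigma / sqrt(n)
  cfgN <- simulationConfig(
    noise = list(lambda = 0.06, phi = 0.7, sigma = 2, subjectCV = 0),
    standard = list(amplitude = 0, latency = 0.1, width = 0.025,
                    spread = 0.02, trunc = 0.042))
  ep <- simulateSubject(cfgN, lay, "musician", "s1", 8,
                        trialsPerDeviant = 200, conditions = "STD")
  av <- averageCondition(ep, "STD")
  expect_equal(sqrt(mean(waveData(av)^2)), 2 / sqrt(200), tolerance = 0.1)
})

test_that("the preprocessing chain preserves additivity at kappa zero", {
  lay <- makeLayout(30, seed = 4)
  cfg0 <- zeroNoiseConfig()
  ep <- simulateSubject(cfg0, lay, "musician", "s1", 2, trialsPerDeviant = 8)
  pp <- preprocessPipeline(ep)
  expect_named(pp$evoked, c("STD", deviantTypes()), ignore.order = TRUE)
  empF <- empiricalMMNm(pp$evoked$F, pp$evoked$STD)
  empI <- empiricalMMNm(pp$evoked$I, pp$evoked$STD)
  empFI <- empiricalMMNm(pp$evoked$FI, pp$evoked$STD)
  mod <- modeledMMNm(list(empF, empI))
  expect_lt(max(abs(additivityDifference(empFI, mod))), 1e-8)
  ## deterministic given the input
  pp2 <- preprocessPipeline(ep)
  expect_equal(waveData(pp2$evoked$FI), waveData(pp$evoked$FI))
})
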