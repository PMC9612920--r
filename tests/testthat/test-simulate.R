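test_that("synthetic layouts cover both hemispheres with distinct sites", {
  lay <- makeLayout(51, seed = 1)
  expect_equal(nPairs(lay), 51)
  h <- table(lay@pairs$hemisphere)
  expect_gte(h[["left"]], 20)
  expect_gte(h[["right"]], 20)
  pos <- as.matrix(lay@pairs[, c("x", "y", "z")])
  expect_gt(min(dist(pos)), 0)
  expect_equal(sqrt(rowSums(pos^2)), rep(lay@radius, 51), tolerance = 1e-9)
  expect_identical(makeLayout(51, seed = 1)@pairs, lay@pairs)
  expect_false(identical(makeLayout(51, seed = 2)@pairs, lay@pairs))
  expect_error(makeLayout(9, 1), "nPairs")
})

test_that("component waveforms are Gaussian bumps with the nominal latency", {
  w <- componentWaveform(0.156, 0.03, 5)
  t <- MMNmAdditivity:::timeAxis(250)
  expect_equal(t[which.max(w)], 0.156)
  expect_equal(componentWaveform(0.156, 0.03, 0), rep(0, 126))
  ## discrete integral vs closed form amplitude * width * sqrt(2*pi)
  expect_equal(sum(w) / 250, 5 * 0.03 * sqrt(2 * pi), tolerance = 0.01)
  ## and vs adaptive quadrature of the continuous component
  quad <- integrate(function(x) 5 * exp(-(x - 0.156)^2 / (2 * 0.03^2)),
                    -0.1, 0.4)$value
  expect_equal(sum(w) / 250, quad, tolerance = 0.01)
  expect_error(componentWaveform(0.156, -1, 5), "width")
  expect_error(componentWaveform(0.9, 0.03, 5), "latency")
})

test_that("noise-free evoked fields obey the subadditivity model", {
  lay <- makeLayout(40, seed = 2)
  cfg0 <- zeroNoiseConfig()
  S <- trueEvoked("STD", "musician", cfg0, lay)
  for (dv in c("FI", "IL", "LF", "FIL")) {
    singles <- lapply(deviantConstituents(dv), function(f)
      trueEvoked(f, "musician", cfg0, lay) - S)
    expect_equal(trueEvoked(dv, "musician", cfg0, lay) - S,
                 Reduce(`+`, singles), tolerance = 1e-12)
  }
  cfg1 <- zeroNoiseConfig(c(FI = 1, IL = 1, LF = 1, FIL = 1))
  expect_equal(trueEvoked("FI", "musician", cfg1, lay), S)
  ## multiplicative shrinkage: mismatch scaled by (1 - kappa)
  cfg3 <- zeroNoiseConfig(c(FI = 0.3, IL = 0.3, LF = 0.3, FIL = 0.3))
  m0 <- trueEvoked("FI", "musician", cfg0, lay) - S
  m3 <- trueEvoked("FI", "musician", cfg3, lay) - S
  expect_equal(m3, 0.7 * m0, tolerance = 1e-12)
  expect_error(trueEvoked("FI", "pianist", cfg0, lay), "unknown group")
})

test_that("planar RMS combination recovers the pair-level field magnitude", {
  lay <- makeLayout(30, seed = 3)
  cfg <- zeroNoiseConfig()
  E <- trueEvoked("F", "musician", cfg, lay)
  ev <- methods::new("Evoked", data = E, condition = "F", nTrials = 1,
                     channelNames = rownames(E), fsHz = 250, t0S = -0.1,
                     subjectId = "s", group = "musician", paradigm = "none",
                     combined = FALSE)
  tot <- MMNmAdditivity:::.pairSignal("F", "musician", cfg, lay)
  expect_equal(unname(waveData(combinePlanar(ev, "sum"))), abs(tot),
               tolerance = 1e-12)
  expect_equal(waveData(combinePlanar(ev, "mean")),
               waveData(combinePlanar(ev, "sum")) / sqrt(2),
               tolerance = 1e-12)
})

test_that("simulated trials equal the truth at zero noise and carry the
           specified correlation structure otherwise", {
  lay <- makeLayout(20, seed = 1)
  cfg0 <- zeroNoiseConfig()
  ep <- simulateSubject(cfg0, lay, "musician", "s1", 3,
                        trialsPerDeviant = 8, conditions = c("STD", "F"))
  E <- trueEvoked("F", "musician", cfg0, lay)
  for (tr in which(ep@condition == "F"))
    expect_equal(unname(ep@data[tr, , ]), unname(E), tolerance = 1e-12)

  ## pure-noise config: check spatial covariance and AR(1) over sites
  cfgN <- simulationConfig(
    noise = list(lambda = 0.06, phi = 0.7, sigma = 1, subjectCV = 0),
    standard = list(amplitude = 0, latency = 0.1, width = 0.025,
                    spread = 0.02, trunc = 0.042))
  ep <- simulateSubject(cfgN, lay, "musician", "s1", 7,
                        trialsPerDeviant = 400, conditions = "STD")
  aCh <- ep@data[, seq(1, 40, 2), ]                  # one channel per site
  flat <- matrix(aperm(aCh, c(2, 1, 3)), nrow = 20)
  emp <- stats::cov(t(flat))
  D <- as.matrix(dist(as.matrix(lay@pairs[, c("x", "y", "z")])))
  theo <- exp(-D / 0.06)
  expect_lt(norm(emp - theo, "F") / norm(theo, "F"), 0.15)
  ac1 <- mean(apply(ep@data[, 1, ], 1,
                    function(z) stats::cor(z[-1], z[-length(z)])))
  expect_lt(abs(ac1 - 0.7), 0.05)
})

test_that("jump injection is reproducible and steps exactly once per trial", {
  lay <- makeLayout(15, seed = 1)
  cfg <- zeroNoiseConfig()
  ep <- simulateSubject(cfg, lay, "musician", "s1", 3,
                        trialsPerDeviant = 10, conditions = "STD")
  same <- injectJumps(ep, 0, 100, 5)
  expect_equal(same@data, ep@data)
  all_ <- injectJumps(ep, 1, 100, 5)
  expect_equal(sort(all_@misc$jumpTrials), 1:10)
  for (tr in 1:10) {
    d <- all_@data[tr, , ] - ep@data[tr, , ]
    jumped <- which(rowSums(abs(d)) > 0)
    expect_length(jumped, 1)
    expect_equal(sum(abs(diff(d[jumped, ])) > 1e-9), 1)  # one step
  }
  expect_identical(injectJumps(ep, 0.4, 100, 9)@misc$jumpInfo,
                   injectJumps(ep, 0.4, 100, 9)@misc$jumpInfo)
})
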