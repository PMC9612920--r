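test_that("samplewise t statistics match the pooled-variance closed form", {
  a <- array(c(1, 2, 3), c(3, 1, 1))
  b <- array(c(2, 3, 4), c(3, 1, 1))
  tv <- samplewiseT(a, b, "independent")
  expect_equal(tv[1, 1], -1.2247, tolerance = 1e-4)
  expect_equal(attr(tv, "df"), 4)
  ## agrees with t.test(var.equal = TRUE) on random maps
  set.seed(5)
  x <- array(rnorm(6 * 2 * 3), c(6, 2, 3))
  y <- array(rnorm(5 * 2 * 3), c(5, 2, 3))
  tv <- samplewiseT(x, y, "independent")
  expect_equal(tv[2, 3],
               stats::t.test(x[, 2, 3], y[, 2, 3],
                             var.equal = TRUE)$statistic[[1]])
  ## invariant to adding a common constant
  expect_equal(samplewiseT(x + 5, y + 5, "independent"), tv)
  ## identical groups give zero everywhere
  expect_equal(max(abs(samplewiseT(x, x, "independent"))), 0)
  ## dependent design is the one-sample t on differences
  d <- array(rnorm(7 * 2 * 3), c(7, 2, 3))
  td <- samplewiseT(d, design = "dependent")
  expect_equal(td[1, 2], stats::t.test(d[, 1, 2])$statistic[[1]])
  expect_equal(attr(td, "df"), 6)
  expect_error(samplewiseT(array(1, c(1, 2, 2)), array(1, c(1, 2, 2)),
                           "independent"), "2 subjects")
})

test_that("adjacency derives from linear distance with sane thresholds", {
  lay <- makeLayout(20, seed = 2)
  D <- as.matrix(dist(as.matrix(lay@pairs[, c("x", "y", "z")])))
  adj <- buildAdjacency(lay)
  oracle <- D > 0 & D <= adj@thresholdM
  dimnames(oracle) <- dimnames(adj@matrix)
  expect_equal(adj@matrix, oracle)
  expect_error(buildAdjacency(lay, thresholdM = min(D[D > 0]) * 0.9),
               "isolated")
  full <- buildAdjacency(lay, thresholdM = max(D) + 1)
  expect_true(all(full@matrix[upper.tri(full@matrix)]))
  auto <- buildAdjacency(lay)
  expect_gte(mean(rowSums(auto@matrix)), 3)
})

test_that("cluster formation respects connectivity and the two-sensor rule", {
  adj <- chainAdjacency(3)
  tm <- matrix(0, 3, 4)
  attr(tm, "df") <- 10
  expect_length(formClusters(tm, 10, 0.05, adj), 0)
  ## planted block spanning two neighboring pairs
  tm[1, 2] <- tm[2, 2] <- tm[2, 3] <- 5
  cl <- formClusters(tm, 10, 0.05, adj)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$sumT, 15)
  expect_equal(cl[[1]]$sign, 1)
  expect_equal(nrow(cl[[1]]$cells), 3)
  ## samples confined to one pair are discarded
  tm2 <- matrix(0, 3, 4); tm2[1, ] <- 5; attr(tm2, "df") <- 10
  expect_length(formClusters(tm2, 10, 0.05, adj), 0)
  ## samples on two non-neighboring pairs at the same time: not connected
  tm3 <- matrix(0, 3, 4); tm3[1, 2] <- tm3[3, 2] <- 5
  expect_length(formClusters(tm3, 10, 0.05, adj), 0)
  ## opposite signs never join
  tm4 <- matrix(0, 3, 4); tm4[1, 2] <- 5; tm4[2, 2] <- -5
  expect_length(formClusters(tm4, 10, 0.05, adj), 0)
})

test_that("cluster formation matches the graph-components oracle on random
           grids", {
  set.seed(42)
  for (rep in 1:25) {
    nP <- sample(4:6, 1); nT <- sample(6:10, 1)
    adj <- chainAdjacency(nP, chord13 = runif(1) < 0.5)
    tm <- matrix(rnorm(nP * nT, sd = 2), nP, nT)
    mine <- formClusters(tm, df = 10, alphaForming = 0.05, adjacency = adj)
    orc <- igraphClusterOracle(tm, stats::qt(0.975, 10), adj@matrix)
    expect_setequal(clusterKeys(mine, nP),
                    vapply(orc, paste, "", collapse = ","))
    ## summed t recomputed from membership
    for (cl in mine)
      expect_equal(cl$sumT, sum(tm[cbind(cl$cells[, "pair"],
                                         cl$cells[, "time"])]))
  }
})

test_that("maxsum statistics keep the two tails separate", {
  cl <- list(list(cells = cbind(pair = 1, time = 1), sign = 1, sumT = 5),
             list(cells = cbind(pair = 1, time = 3), sign = 1, sumT = 7),
             list(cells = cbind(pair = 2, time = 1), sign = -1, sumT = -9))
  expect_equal(clusterStat(cl), c(pos = 7, neg = -9))
  expect_equal(clusterStat(cl[1]), c(pos = 5, neg = 0))
  expect_equal(clusterStat(list()), c(pos = 0, neg = 0))
})

test_that("permutation tests are seeded, exchangeable and switch to
           exhaustive enumeration", {
  adj <- chainAdjacency(4)
  set.seed(8)
  sig <- array(rnorm(8 * 4 * 10), c(8, 4, 10))
  sig[1:4, 1:2, 3:6] <- sig[1:4, 1:2, 3:6] + 2.5
  a <- sig[1:4, , , drop = FALSE]
  b <- sig[5:8, , , drop = FALSE]
  spec <- testSpec("independent", nPerm = 1000, seed = 2)
  ## auto-switch: C(8,4) = 70 < nPerm
  expect_warning(res <- permutationTest(a, b, spec, adj), "exhaustive")
  expect_true(res@exhaustive)
  expect_equal(res@nPerm, 70)
  ## exhaustive dependent: 2^n sign patterns
  d <- array(rnorm(5 * 4 * 10), c(5, 4, 10))
  expect_warning(
    resD <- permutationTest(d, spec = testSpec("dependent", nPerm = 100,
                                               seed = 1),
                            adjacency = adj), "exhaustive")
  expect_equal(resD@nPerm, 32)
  ## same seed, same result; different seed, different null
  mc1 <- permutationTest(a, b, spec, adj, forceMC = TRUE)
  mc2 <- permutationTest(a, b, spec, adj, forceMC = TRUE)
  expect_identical(pValues(mc1), pValues(mc2))
  expect_identical(mc1@nullMax, mc2@nullMax)
  ## p-values in (0, 1], never zero
  expect_true(all(pValues(mc1) > 0 & pValues(mc1) <= 1))
  ## label swap flips cluster signs but keeps p-values
  swapped <- permutationTest(b, a, spec, adj, forceMC = TRUE)
  expect_equal(sort(pValues(swapped)), sort(pValues(mc1)))
  expect_equal(clusterStat(swapped@clusters)[["pos"]],
               -clusterStat(mc1@clusters)[["neg"]])
  ## identical groups: no signal, so any cluster is a null fluctuation
  same <- permutationTest(a, a + 1e-9, spec, adj, forceMC = TRUE)
  expect_true(length(same@clusters) == 0 || all(pValues(same) > 0.5))
  ## p-values invariant to channel reordering
  perm <- c(3, 1, 4, 2)
  adjP <- methods::new("Adjacency", matrix = adj@matrix[perm, perm],
                       pairIds = 1:4, thresholdM = 1)
  resP <- permutationTest(a[, perm, , drop = FALSE],
                          b[, perm, , drop = FALSE], spec, adjP,
                          forceMC = TRUE)
  expect_equal(sort(pValues(resP)), sort(pValues(mc1)))
})

test_that("exhaustive enumeration has the advertised cardinalities", {
  adj <- chainAdjacency(3)
  a <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  b <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  res <- exhaustivePermutation(a, b, testSpec("independent", seed = 1), adj)
  expect_equal(res@nPerm, 20)                      # C(6, 3)
  d <- array(rnorm(10 * 3 * 4), c(10, 3, 4))
  resD <- exhaustivePermutation(d, spec = testSpec("dependent", seed = 1),
                                adjacency = adj)
  expect_equal(resD@nPerm, 1024)                   # 2^10
  expect_error(exhaustivePermutation(array(0, c(8, 3, 4)),
                                     array(0, c(8, 3, 4)),
                                     testSpec("independent", seed = 1), adj),
               "<= 12")
})

test_that("the corrected alpha follows the two-sided Bonferroni rule", {
  expect_equal(bonferroniAlpha(0.05, 4), 0.00625)
  expect_equal(bonferroniAlpha(0.05, 1), 0.025)
  alphas <- vapply(1:8, function(k) bonferroniAlpha(0.05, k), 0)
  expect_true(all(diff(alphas) < 0))
})

test_that("high-level additivity tests detect planted group differences", {
  lay <- makeLayout(51, seed = 1)
  ## strong, low-noise effect so a single seeded run is conclusive
  simCfg <- simulationConfig(
    kappa = list(musician = c(FI = 0.5, IL = 0, LF = 0.5, FIL = 0.5),
                 nonmusician = ZERO_KAPPA),
    noise = list(lambda = 0.06, phi = 0.7, sigma = 10, subjectCV = 0.1))
  sel <- MMNmAdditivity:::.noiselessSelection(simCfg, lay)
  waves <- evokedCohortWaves(simCfg, lay, nPerGroup = 8, "FI",
                             trials = 144, seed = 31)
  spec <- testSpec("independent", nPerm = 800, seed = 7)
  res <- interactionTest(waves, "FI", lay, sel, spec,
                         groups = c("musician", "nonmusician"))
  expect_true(any(pValues(res) <= 0.025))
  ## subadditivity in musicians shows as a negative cluster
  sig <- res@clusters[[which.min(pValues(res))]]
  expect_equal(sig$sign, -1)
  ## simple effect present in musicians, absent in controls
  resM <- suppressWarnings(
    simpleEffectTest(waves, "FI", "musician", lay, sel,
                     testSpec("dependent", nPerm = 800, seed = 8)))
  expect_true(any(pValues(resM) <= 0.025))
  ## identical empirical and modeled waves: no supra-threshold samples
  kinds <- vapply(waves, function(w) w@kind, "")
  empOnly <- waves[kinds == "empirical"]
  dup <- lapply(empOnly, function(w) { w@kind <- "modeled"; w })
  resNull <- suppressWarnings(
    simpleEffectTest(c(empOnly, dup), "FI", "musician", lay, sel,
                     testSpec("dependent", nPerm = 200, seed = 9)))
  expect_length(resNull@clusters, 0)
})

test_that("presence and ordering tests see the built-in mismatch hierarchy", {
  lay <- makeLayout(51, seed = 1)
  simCfg <- simulationConfig(
    kappa = list(musician = ZERO_KAPPA, nonmusician = ZERO_KAPPA),
    noise = list(lambda = 0.06, phi = 0.7, sigma = 10, subjectCV = 0.1))
  sel <- MMNmAdditivity:::.noiselessSelection(simCfg, lay)
  seeds <- MMNmAdditivity:::deriveSeeds(77, 8)
  evokeds <- list(); waves <- list()
  for (s in 1:8) {
    ev <- simulateSubjectEvoked(simCfg, lay, "musician",
                                sprintf("m%02d", s), seeds[s],
                                trialsPerDeviant = 144,
                                conditions = c("STD", "F", "FI"))
    ev <- lapply(ev, function(e) baselineCorrect(combinePlanar(e)))
    evokeds <- c(evokeds, ev)
    waves <- c(waves, list(empiricalMMNm(ev$F, ev$STD),
                           empiricalMMNm(ev$FI, ev$STD)))
  }
  spec <- testSpec("dependent", nPerm = 600, seed = 3)
  pres <- suppressWarnings(
    presenceTest(evokeds, "F", "musician", lay, sel, spec))
  expect_true(any(pValues(pres) <= 0.025))
  ## double exceeds single under additivity (one-sided)
  ord <- suppressWarnings(
    orderingTest(waves, "FI", "F", lay, sel, spec))
  expect_true(any(pValues(ord) <= 0.025))
  expect_true(all(vapply(ord@clusters, function(cl) cl$sign, 0) > 0))
})
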