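## Shared fixtures and independent oracles, built in code at test time.

ZERO_KAPPA <- c(FI = 0, IL = 0, LF = 0, FIL = 0)

zeroNoiseConfig <- function(kappaMus = ZERO_KAPPA) {
  simulationConfig(noise = list(lambda = 0.06, phi = 0.7, sigma = 0,
                                subjectCV = 0),
                   kappa = list(musician = kappaMus,
                                nonmusician = ZERO_KAPPA))
}

defaultConfig <- function(kappaMus = c(FI = 0.4, IL = 0, LF = 0.4,
                                       FIL = 0.4)) {
  simulationConfig(kappa = list(musician = kappaMus,
                                nonmusician = ZERO_KAPPA))
}

## A chain adjacency over nP pairs (1-2-3-...), optionally with a 1-3 chord.
chainAdjacency <- function(nP, chord13 = FALSE) {
  A <- matrix(FALSE, nP, nP)
  for (i in seq_len(nP - 1)) A[i, i + 1] <- A[i + 1, i] <- TRUE
  if (chord13) A[1, 3] <- A[3, 1] <- TRUE
  methods::new("Adjacency", matrix = A, pairIds = seq_len(nP),
               thresholdM = 1)
}

## Independent connected-components oracle for cluster formation, built on
## igraph; applies the same minimum-two-neighbor-sensors admissibility rule.
## Returns a list of sorted linear cell-index vectors.
igraphClusterOracle <- function(tMap, thr, A) {
  nP <- nrow(tMap)
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(if (sgn > 0) tMap > thr else tMap < -thr)
    if (length(supra) == 0) next
    g <- igraph::make_empty_graph(length(supra), directed = FALSE)
    if (length(supra) > 1) {
      edges <- integer(0)
      for (i in seq_along(supra)) for (j in seq_len(i - 1L)) {
        pi_ <- (supra[i] - 1) %% nP + 1; ti <- (supra[i] - 1) %/% nP + 1
        pj <- (supra[j] - 1) %% nP + 1; tj <- (supra[j] - 1) %/% nP + 1
        if ((pi_ == pj && abs(ti - tj) == 1) || (ti == tj && A[pi_, pj]))
          edges <- c(edges, i, j)
      }
      if (length(edges)) g <- igraph::add_edges(g, edges)
    }
    for (cp in igraph::groups(igraph::components(g))) {
      cells <- supra[as.integer(cp)]
      u <- unique((cells - 1) %% nP + 1)
      if (length(u) > 1 && any(A[u, u]))
        out[[length(out) + 1L]] <- sort(cells)
    }
  }
  out
}

## Canonical string form of a cluster list for set comparison.
clusterKeys <- function(clusters, nP) {
  vapply(clusters, function(cl) {
    cells <- if (is.matrix(cl$cells))
      (cl$cells[, "time"] - 1) * nP + cl$cells[, "pair"]
    else cl$cells
    paste(sort(cells), collapse = ",")
  }, "")
}

## Least-squares amplitude of a sinusoid at frequency f in series y.
sineAmplitude <- function(y, f, t, idx = seq_along(t)) {
  X <- cbind(sin(2 * pi * f * t[idx]), cos(2 * pi * f * t[idx]))
  cf <- stats::coef(stats::lm(y[idx] ~ X - 1))
  sqrt(sum(cf^2))
}

## Designed two-pass Butterworth band-pass power gain at frequency f.
designGain2 <- function(f, fsHz = 250, lowHz = 1, highHz = 40, order = 4) {
  bf <- signal::butter(order, c(lowHz, highHz) / (fsHz / 2), type = "pass")
  z <- exp(-1i * 2 * pi * f / fsHz)
  Mod(sum(bf$b * z^(seq_along(bf$b) - 1)) /
        sum(bf$a * z^(seq_along(bf$a) - 1)))^2
}

## Evoked-level cohort of combined MMNm waves (both kinds, both groups)
## for one deviant type; small and fast for test purposes.
evokedCohortWaves <- function(simCfg, layout, nPerGroup, deviantType,
                              trials, seed) {
  seeds <- MMNmAdditivity:::deriveSeeds(seed, 2 * nPerGroup)
  waves <- list()
  k <- 0L
  for (group in names(simCfg$kappa)) {
    for (s in seq_len(nPerGroup)) {
      k <- k + 1L
      ev <- simulateSubjectEvoked(simCfg, layout, group,
                                  sprintf("%s%02d", substr(group, 1, 1), s),
                                  seeds[k], trialsPerDeviant = trials,
                                  conditions = c("STD",
                                                 deviantConstituents(deviantType),
                                                 deviantType))
      ev <- lapply(ev, function(e) baselineCorrect(combinePlanar(e)))
      singles <- lapply(deviantConstituents(deviantType), function(f)
        empiricalMMNm(ev[[f]], ev$STD))
      waves <- c(waves,
                 list(empiricalMMNm(ev[[deviantType]], ev$STD),
                      modeledMMNm(singles)))
    }
  }
  waves
}
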