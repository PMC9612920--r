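## Nonparametric spatiotemporal cluster-based permutation testing:
## samplewise t maps, cluster formation over the sensor-time grid with a
## minimum-two-neighbor-sensors rule, per-sign maxsum statistics, Monte
## Carlo and exhaustive null distributions.

#' Specification of a cluster permutation test
#'
#' @param design `"independent"` (between-group) or `"dependent"`
#'   (within-subject paired).
#' @param nPerm Number of random permutations (default 10000; >= 100).
#' @param alphaForming Cluster-forming alpha: samples exceeding the
#'   two-tailed t critical value at this level enter clusters (default 0.05).
#' @param alphaInference Per-tail inference alpha a cluster p-value is
#'   compared against (default 0.025, i.e. a two-sided level of 0.05;
#'   Bonferroni over the four additivity comparisons gives 0.00625, see
#'   [bonferroniAlpha()]).
#' @param windowS Analysis window in seconds (default 100-300 ms).
#' @param tail `"both"` (default, sign-separated nulls), `"pos"` or `"neg"`
#'   for directional tests.
#' @param seed RNG seed for the permutation stream.
#' @return A list of class `TestSpec`.
#' @export
testSpec <- function(design = c("independent", "dependent"), nPerm = 10000,
                     alphaForming = 0.05, alphaInference = 0.025,
                     windowS = c(0.100, 0.300),
                     tail = c("both", "pos", "neg"), seed = 1L) {
  design <- match.arg(design)
  tail <- match.arg(tail)
  if (nPerm < 100) stop("nPerm must be >= 100")
  structure(list(design = design, nPerm = as.integer(nPerm),
                 alphaForming = alphaForming,
                 alphaInference = alphaInference, windowS = windowS,
                 tail = tail, seed = as.integer(seed)), class = "TestSpec")
}

#' Bonferroni-corrected per-tail alpha
#'
#' Halves a two-sided base alpha and divides by the number of comparisons:
#' `(base / 2) / nTests`. With the defaults this gives 0.05 / 2 / 4 =
#' 0.00625, the corrected level applied to the four comparisons of modeled
#' and empirical double/triple mismatch responses.
#'
#' @param baseTwoSided Overall two-sided alpha (default 0.05).
#' @param nTests Number of comparisons corrected for (default 4).
#' @return The corrected per-tail alpha.
#' @examples
#' bonferroniAlpha(0.05, 4)
#' @export
bonferroniAlpha <- function(baseTwoSided = 0.05, nTests = 4) {
  stopifnot(baseTwoSided > 0, nTests >= 1)
  (baseTwoSided / 2) / nTests
}

#' Sensor neighborhood structure from linear distance
#'
#' Pairs i, j are neighbors iff `0 < d(i, j) <= thresholdM`. When a
#' selection is given, the structure is restricted to the selected pairs.
#' When `thresholdM` is `NULL`, the smallest distance giving a mean of at
#' least `minMeanNeighbors` neighbors per pair is chosen and recorded.
#'
#' @param layout A [SensorLayout-class].
#' @param selection Optional [SensorSelection-class]; restricts to the 18
#'   analysed pairs.
#' @param thresholdM Distance threshold in meters, or `NULL` to choose
#'   automatically.
#' @param minMeanNeighbors Target mean neighbor count for the automatic
#'   threshold (default 3).
#' @return An [Adjacency-class].
#' @export
buildAdjacency <- function(layout, selection = NULL, thresholdM = NULL,
                           minMeanNeighbors = 3) {
  p <- layout@pairs
  ids <- if (is.null(selection)) p$pair_id else selectedPairs(selection)
  rows <- match(ids, p$pair_id)
  D <- as.matrix(stats::dist(cbind(p$x[rows], p$y[rows], p$z[rows])))
  if (is.null(thresholdM)) {
    cand <- sort(unique(D[upper.tri(D)]))
    nn <- vapply(cand, function(th) mean(rowSums(D <= th) - 1), 0)
    thresholdM <- cand[which(nn >= minMeanNeighbors)[1]]
    if (is.na(thresholdM)) stop("no threshold reaches the neighbor target")
  }
  if (thresholdM <= 0) stop("thresholdM must be positive")
  A <- D > 0 & D <= thresholdM
  diag(A) <- FALSE
  if (any(rowSums(A) == 0))
    stop("isolated pair(s) at this threshold; increase thresholdM")
  dimnames(A) <- list(ids, ids)
  methods::new("Adjacency", matrix = A, pairIds = as.integer(ids),
               thresholdM = thresholdM)
}

#' Samplewise t statistics
#'
#' Pooled-variance two-sample t (independent design; df = n1 + n2 - 2) or
#' one-sample t on paired differences (dependent design; df = n - 1),
#' computed for every sensor-time sample.
#'
#' @param a Array of subject maps, subjects x pairs x time (for the
#'   dependent design: the paired difference maps).
#' @param b Second group's array (independent design only).
#' @param design `"independent"` or `"dependent"`.
#' @return Matrix pairs x time of t values, with a `df` attribute.
#' @export
samplewiseT <- function(a, b = NULL, design = c("independent", "dependent")) {
  design <- match.arg(design)
  dm <- dim(a)[-1]
  A <- matrix(a, nrow = dim(a)[1])
  if (design == "independent") {
    if (is.null(b)) stop("independent design needs two groups")
    B <- matrix(b, nrow = dim(b)[1])
    n1 <- nrow(A); n2 <- nrow(B)
    if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
    sp2 <- ((n1 - 1) * apply(A, 2, stats::var) +
              (n2 - 1) * apply(B, 2, stats::var)) / (n1 + n2 - 2)
    tv <- (colMeans(A) - colMeans(B)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    n <- nrow(A)
    if (n < 2) stop("need at least 2 subjects")
    tv <- colMeans(A) / sqrt(apply(A, 2, stats::var) / n)
    df <- n - 1
  }
  tv[!is.finite(tv)] <- 0
  out <- matrix(tv, dm[1], dm[2])
  attr(out, "df") <- df
  out
}

## Adjacency matrix -> list of neighbor indices per pair (row index space).
.adjList <- function(adjMat) {
  lapply(seq_len(nrow(adjMat)), function(i) which(adjMat[i, ]))
}

## Connected components of supra-threshold samples. Two samples connect iff
## same pair and adjacent time samples, or same time sample and neighboring
## pairs. Returns per sign a list of integer cell vectors
## (cell = pair + nPairs * (time - 1)).
.clusterScan <- function(tMap, thr, adjList) {
  nP <- nrow(tMap); nT <- ncol(tMap)
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- if (sgn > 0) tMap > thr else tMap < -thr
    idx <- which(supra)
    if (length(idx) == 0) next
    visited <- logical(nP * nT)
    for (s in idx) {
      if (visited[s]) next
      stack <- s
      visited[s] <- TRUE
      comp <- integer(0)
      while (length(stack)) {
        cur <- stack[length(stack)]
        stack <- stack[-length(stack)]
        comp[length(comp) + 1L] <- cur
        p <- ((cur - 1L) %% nP) + 1L
        tt <- ((cur - 1L) %/% nP) + 1L
        nbr <- integer(0)
        if (tt > 1L) nbr <- cur - nP
        if (tt < nT) nbr <- c(nbr, cur + nP)
        adj <- adjList[[p]]
        if (length(adj)) nbr <- c(nbr, cur - p + adj)
        nbr <- nbr[supra[nbr] & !visited[nbr]]
        if (length(nbr)) {
          visited[nbr] <- TRUE
          stack <- c(stack, nbr)
        }
      }
      out[[length(out) + 1L]] <- list(cells = comp, sign = sgn)
    }
  }
  out
}

## Admissibility: a cluster must contain at least two distinct, mutually
## neighboring pairs.
.admissible <- function(cells, nP, adjMat) {
  u <- unique(((cells - 1L) %% nP) + 1L)
  length(u) > 1L && any(adjMat[u, u])
}

#' Form spatiotemporal clusters from a t map
#'
#' Thresholds the t map at the two-tailed critical value of
#' `alphaForming`, connects supra-threshold samples of the same sign that
#' are neighbors in time (same pair, adjacent samples) and/or space (same
#' sample, neighboring pairs), and discards assemblies that do not contain
#' at least two mutually neighboring pairs.
#'
#' @param tMap Matrix pairs x time (as from [samplewiseT()]).
#' @param df Degrees of freedom for the critical value (taken from the
#'   `df` attribute of `tMap` when missing).
#' @param alphaForming Cluster-forming alpha (default 0.05).
#' @param adjacency An [Adjacency-class] whose rows match the tMap rows.
#' @return List of clusters: `cells` (matrix with columns `pair`, `time`),
#'   `sign`, `sumT`. Empty list when nothing is supra-threshold.
#' @export
formClusters <- function(tMap, df = attr(tMap, "df"), alphaForming = 0.05,
                         adjacency) {
  stopifnot(is(adjacency, "Adjacency"), df >= 1)
  if (nrow(tMap) != nrow(adjacency@matrix))
    stop("tMap rows must match the adjacency")
  thr <- stats::qt(1 - alphaForming / 2, df)
  raw <- .clusterScan(tMap, thr, .adjList(adjacency@matrix))
  nP <- nrow(tMap)
  keep <- Filter(function(cl) .admissible(cl$cells, nP, adjacency@matrix),
                 raw)
  lapply(keep, function(cl) {
    list(cells = cbind(pair = ((cl$cells - 1L) %% nP) + 1L,
                       time = ((cl$cells - 1L) %/% nP) + 1L),
         sign = cl$sign, sumT = sum(tMap[cl$cells]))
  })
}

#' Per-sign maxsum cluster statistic
#'
#' @param clusters List as returned by [formClusters()].
#' @return Named vector `pos` (max summed t over positive clusters) and
#'   `neg` (min over negative clusters); 0 when a sign has no clusters.
#' @export
clusterStat <- function(clusters) {
  sums <- vapply(clusters, function(cl) cl$sumT, 0)
  signs <- vapply(clusters, function(cl) cl$sign, 0)
  c(pos = if (any(signs > 0)) max(sums[signs > 0]) else 0,
    neg = if (any(signs < 0)) min(sums[signs < 0]) else 0)
}

## Lean per-permutation statistic: per-sign maxsum with admissibility,
## without materialising cluster membership.
.permMaxSum <- function(tMap, thr, adjList, adjMat) {
  raw <- .clusterScan(tMap, thr, adjList)
  nP <- nrow(tMap)
  best <- c(pos = 0, neg = 0)
  for (cl in raw) {
    if (!.admissible(cl$cells, nP, adjMat)) next
    s <- sum(tMap[cl$cells])
    if (cl$sign > 0) best["pos"] <- max(best["pos"], s)
    else best["neg"] <- min(best["neg"], s)
  }
  best
}

## Null t maps for a batch of independent-design relabelings.
## X: n x p data, ind: n x B 0/1 indicator of pseudo-group-1 membership.
.tBatchIndependent <- function(X, ind, n1, n2) {
  S1 <- crossprod(X, ind)                 # p x B group-1 sums
  Q1 <- crossprod(X^2, ind)
  St <- colSums(X); Qt <- colSums(X^2)
  m1 <- S1 / n1
  m2 <- (St - S1) / n2
  ss1 <- Q1 - S1^2 / n1
  ss2 <- (Qt - Q1) - (St - S1)^2 / n2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  tv <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tv[!is.finite(tv)] <- 0
  tv
}

## Null t maps for a batch of dependent-design sign flips.
## D: n x p paired differences, sgn: n x B of +/-1.
.tBatchDependent <- function(D, sgn) {
  n <- nrow(D)
  S <- crossprod(D, sgn)                  # p x B
  m <- S / n
  v <- (colSums(D^2) - S^2 / n) / (n - 1)
  tv <- m / sqrt(v / n)
  tv[!is.finite(tv)] <- 0
  tv
}

.asSubjectMatrix <- function(a) matrix(a, nrow = dim(a)[1])

## All relabelings for exhaustive enumeration.
.allIndicators <- function(n, n1) {
  cmb <- utils::combn(n, n1)
  ind <- matrix(0, n, ncol(cmb))
  ind[cbind(as.vector(cmb), rep(seq_len(ncol(cmb)), each = n1))] <- 1
  ind
}

.allSignPatterns <- function(n) {
  B <- 2^n
  sgn <- matrix(1, n, B)
  for (i in seq_len(n))
    sgn[i, ] <- rep(rep(c(1, -1), each = 2^(i - 1)), length.out = B)
  sgn
}

.buildClusterResult <- function(tMap, spec, adjacency, nullMax, nPermUsed,
                                exhaustive, df, info) {
  clusters <- formClusters(tMap, df, spec$alphaForming, adjacency)
  if (spec$tail == "pos")
    clusters <- Filter(function(cl) cl$sign > 0, clusters)
  if (spec$tail == "neg")
    clusters <- Filter(function(cl) cl$sign < 0, clusters)
  add <- if (exhaustive) 0 else 1
  pv <- vapply(clusters, function(cl) {
    if (cl$sign > 0)
      (add + sum(nullMax[, "pos"] >= cl$sumT - 1e-12)) / (nPermUsed + add)
    else
      (add + sum(nullMax[, "neg"] <= cl$sumT + 1e-12)) / (nPermUsed + add)
  }, 0)
  methods::new("ClusterResult", clusters = clusters, pValues = pv,
               observedMax = clusterStat(clusters), nullMax = nullMax,
               nPerm = nPermUsed, exhaustive = exhaustive,
               seed = spec$seed, alphaForming = spec$alphaForming,
               design = spec$design, info = info)
}

#' Cluster-based permutation test
#'
#' Computes the observed samplewise t map and its spatiotemporal clusters,
#' then builds a Monte Carlo null distribution of the per-sign maxsum
#' cluster statistic by recomputing t maps and clusters under `nPerm`
#' random permutations: group-label exchanges for the independent design,
#' per-subject sign flips of the paired differences for the dependent
#' design. Cluster p-values use the positively biased, validity-guaranteeing
#' estimator `(b + 1) / (m + 1)`. When `nPerm` meets or exceeds the number
#' of distinct relabelings the test switches (with a warning) to exhaustive
#' enumeration with exact p-values.
#'
#' @param a Subjects x pairs x time array: group 1 (independent) or the
#'   paired difference maps (dependent).
#' @param b Group 2 array (independent design only).
#' @param spec A [testSpec()].
#' @param adjacency An [Adjacency-class] matching the pair dimension.
#' @param forceMC Keep Monte Carlo sampling even when exhaustive
#'   enumeration would be possible (used to validate the Monte Carlo
#'   approximation against the exact reference).
#' @param info Optional metadata list stored in the result.
#' @return A [ClusterResult-class].
#' @export
permutationTest <- function(a, b = NULL, spec, adjacency, forceMC = FALSE,
                            info = list()) {
  stopifnot(inherits(spec, "TestSpec"))
  nP <- dim(a)[2]; nT <- dim(a)[3]
  if (nP != nrow(adjacency@matrix)) stop("pair dimension mismatch")
  adjList <- .adjList(adjacency@matrix)
  adjMat <- adjacency@matrix
  if (spec$design == "independent") {
    if (is.null(b)) stop("independent design needs two groups")
    X <- rbind(.asSubjectMatrix(a), .asSubjectMatrix(b))
    n1 <- dim(a)[1]; n2 <- dim(b)[1]; n <- n1 + n2
    df <- n - 2
    tObs <- samplewiseT(a, b, "independent")
    nDistinct <- choose(n, n1)
  } else {
    D <- .asSubjectMatrix(a)
    n <- nrow(D)
    df <- n - 1
    tObs <- samplewiseT(a, design = "dependent")
    nDistinct <- 2^n
  }
  thr <- stats::qt(1 - spec$alphaForming / 2, df)
  exhaustive <- !forceMC && spec$nPerm >= nDistinct
  if (exhaustive)
    warning("nPerm >= ", nDistinct,
            " distinct relabelings; switching to exhaustive enumeration")
  if (spec$design == "independent") {
    IND <- if (exhaustive) .allIndicators(n, n1) else
      withSeed(spec$seed,
               vapply(seq_len(spec$nPerm), function(i) {
                 v <- numeric(n); v[sample.int(n, n1)] <- 1; v
               }, numeric(n)))
    B <- ncol(IND)
    TV <- .tBatchIndependent(X, IND, n1, n2)
  } else {
    SGN <- if (exhaustive) .allSignPatterns(n) else
      withSeed(spec$seed,
               matrix(sample(c(-1, 1), n * spec$nPerm, replace = TRUE),
                      n, spec$nPerm))
    B <- ncol(SGN)
    TV <- .tBatchDependent(D, SGN)
  }
  nullMax <- matrix(0, B, 2, dimnames = list(NULL, c("pos", "neg")))
  tm <- matrix(0, nP, nT)
  for (i in seq_len(B)) {
    tm[] <- TV[, i]
    nullMax[i, ] <- .permMaxSum(tm, thr, adjList, adjMat)
  }
  attr(tObs, "df") <- df
  .buildClusterResult(tObs, spec, adjacency, nullMax, B, exhaustive, df,
                      info)
}

#' Exhaustive permutation test (small-sample oracle)
#'
#' Enumerates every distinct relabeling — all `choose(n, n1)` group
#' assignments for the independent design (total subjects <= 12) or all
#' `2^n` sign patterns for the dependent design (n <= 14) — and reports
#' exact cluster p-values.
#'
#' @inheritParams permutationTest
#' @return A [ClusterResult-class] with `exhaustive = TRUE`.
#' @export
exhaustivePermutation <- function(a, b = NULL, spec, adjacency,
                                  info = list()) {
  if (spec$design == "independent") {
    n <- dim(a)[1] + dim(b)[1]
    if (n > 12) stop("exhaustive independent enumeration limited to n <= 12")
    nDistinct <- choose(n, dim(a)[1])
  } else {
    n <- dim(a)[1]
    if (n > 14) stop("exhaustive dependent enumeration limited to n <= 14")
    nDistinct <- 2^n
  }
  spec$nPerm <- as.integer(nDistinct)
  suppressWarnings(
    permutationTest(a, b, spec, adjacency, forceMC = FALSE, info = info))
}

#' Significant clusters at an alpha level
#'
#' @param result A [ClusterResult-class].
#' @param alpha Per-tail alpha (default the 0.025 two-sided convention).
#' @return Logical vector over the result's clusters.
#' @export
significantClusters <- function(result, alpha = 0.025) {
  pValues(result) <= alpha
}
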