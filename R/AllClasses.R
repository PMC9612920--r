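## S4 classes for the MMNm additivity pipeline.

#' SensorLayout: planar-gradiometer pair geometry
#'
#' Positions of gradiometer pairs on an idealised upper-hemisphere helmet
#' (head coordinates, meters), hemisphere labels, and the fixed per-site
#' combination phase used when projecting a field magnitude onto the two
#' orthogonal gradiometers of a pair.
#'
#' @slot pairs data.frame with columns `pair_id`, `name`, `name_a`, `name_b`,
#'   `x`, `y`, `z`, `hemisphere` (`"left"`, `"right"` or `"midline"`) and
#'   `psi` (combination phase, radians).
#' @slot radius Helmet radius in meters.
#' @slot hotspots List with 3-vectors `left` and `right`: centers of the
#'   temporal regions where mismatch topographies peak.
#' @slot seed Integer seed the layout was built from.
#' @export
setClass("SensorLayout",
  representation(pairs = "data.frame", radius = "numeric",
                 hotspots = "list", seed = "integer"))

setValidity("SensorLayout", function(object) {
  p <- object@pairs
  need <- c("pair_id", "name", "name_a", "name_b", "x", "y", "z",
            "hemisphere", "psi")
  if (!all(need %in% names(p))) return("pairs is missing required columns")
  if (anyDuplicated(p[, c("x", "y", "z")])) return("positions must be unique")
  if (any(p$name_a == p$name_b)) return("each pair needs two distinct channels")
  bad <- (p$hemisphere == "left" & p$x > 0) | (p$hemisphere == "right" & p$x < 0)
  if (any(bad)) return("hemisphere labels inconsistent with lateral coordinate")
  TRUE
})

#' BlockSequence: tone-by-tone schedule of one paradigm block
#'
#' @slot paradigm `"complex"` (Alberti-bass musical multi-feature) or
#'   `"simple"` (classical oddball control).
#' @slot blockId Block identifier.
#' @slot events data.frame with one row per tone: `index`, `onset_s`, `role`
#'   (`"standard"`/`"deviant"`), `deviant_type`, `pitch_index` (0-11),
#'   `pitch_hz`, `pattern_position` (1-4, complex only), `pattern_id`,
#'   `is_analysis_standard`.
#' @slot soaS Stimulus onset asynchrony in seconds.
#' @slot seed Integer seed.
#' @export
setClass("BlockSequence",
  representation(paradigm = "character", blockId = "character",
                 events = "data.frame", soaS = "numeric", seed = "integer"))

setValidity("BlockSequence", function(object) {
  e <- object@events
  if (!object@paradigm %in% c("complex", "simple")) return("bad paradigm")
  if (nrow(e) > 1) {
    d <- diff(e$onset_s)
    if (any(d <= 0)) return("onsets must be strictly increasing")
    if (any(abs(d - object@soaS) > 1e-9)) return("onsets must step by the SOA")
  }
  if (any(e$role == "deviant" & e$deviant_type == "STD"))
    return("deviant rows must carry a deviant type")
  if (any(e$is_analysis_standard & e$role != "standard"))
    return("analysis standards must be standards")
  TRUE
})

#' EpochSet: trials x channels x time array with condition metadata
#'
#' @slot data Numeric array, trials x channels x time.
#' @slot channelNames Channel names (raw gradiometers, or pair names once
#'   combined).
#' @slot fsHz Sampling rate (Hz).
#' @slot t0S Time of the first sample relative to stimulus onset (seconds).
#' @slot condition Per-trial condition code (`"STD"` or a deviant type).
#' @slot analysisStandard Per-trial flag: standard trials retained for
#'   analysis (the third standard after each deviant).
#' @slot subjectId,group,paradigm Metadata strings.
#' @slot combined Logical: `TRUE` after planar RMS combination.
#' @slot misc List for provenance (seeds, injected-jump bookkeeping, ...).
#' @export
setClass("EpochSet",
  representation(data = "array", channelNames = "character", fsHz = "numeric",
                 t0S = "numeric", condition = "character",
                 analysisStandard = "logical", subjectId = "character",
                 group = "character", paradigm = "character",
                 combined = "logical", misc = "list"))

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be trials x channels x time")
  if (d[2] != length(object@channelNames)) return("channelNames length mismatch")
  if (d[1] != length(object@condition)) return("condition length mismatch")
  if (d[1] != length(object@analysisStandard))
    return("analysisStandard length mismatch")
  if (!all(object@condition %in% .allConditions()))
    return("invalid condition codes")
  TRUE
})

#' Evoked: per-condition trial average
#'
#' @slot data Numeric matrix, channels x time.
#' @slot condition Condition code.
#' @slot nTrials Number of trials averaged.
#' @slot channelNames,fsHz,t0S,subjectId,group,paradigm,combined As in
#'   [EpochSet-class].
#' @export
setClass("Evoked",
  representation(data = "matrix", condition = "character",
                 nTrials = "numeric", channelNames = "character",
                 fsHz = "numeric", t0S = "numeric", subjectId = "character",
                 group = "character", paradigm = "character",
                 combined = "logical"))

setValidity("Evoked", function(object) {
  if (nrow(object@data) != length(object@channelNames))
    return("channelNames length mismatch")
  if (object@nTrials < 1) return("nTrials must be >= 1")
  TRUE
})

#' MMNmWave: mismatch difference wave (combined gradiometers)
#'
#' Either an empirical MMNm (deviant average minus standard average) or a
#' modeled MMNm (sum of the constituent single-deviant empirical MMNms).
#'
#' @slot data Numeric matrix, combined pairs x time.
#' @slot deviantType Deviant code (never `"STD"`; `"MIX"` for pooled grand
#'   averages across conditions).
#' @slot kind `"empirical"`, `"modeled"` or `"mixed"`.
#' @slot nTrialsDeviant,nTrialsStandard Trial counts behind the averages.
#' @slot channelNames,fsHz,t0S,subjectId,group,paradigm As in [Evoked-class].
#' @export
setClass("MMNmWave",
  representation(data = "matrix", deviantType = "character",
                 kind = "character", nTrialsDeviant = "numeric",
                 nTrialsStandard = "numeric", channelNames = "character",
                 fsHz = "numeric", t0S = "numeric", subjectId = "character",
                 group = "character", paradigm = "character"))

setValidity("MMNmWave", function(object) {
  if (!object@deviantType %in% c(deviantTypes(), "MIX"))
    return("deviantType must be a deviant code (not STD)")
  if (!object@kind %in% c("empirical", "modeled", "mixed"))
    return("kind must be empirical, modeled or mixed")
  if (object@kind == "modeled" &&
      length(deviantConstituents(object@deviantType)) < 2)
    return("modeled waves exist only for double/triple deviants")
  if (nrow(object@data) != length(object@channelNames))
    return("channelNames length mismatch")
  TRUE
})

#' SensorSelection: peak pairs and neighborhoods used for testing
#'
#' @slot peakPairs Named integer vector (`left`, `right`): peak pair ids.
#' @slot leftPairs,rightPairs Integer vectors of 9 pair ids per hemisphere
#'   (peak plus its 8 nearest same-hemisphere neighbors).
#' @slot windowS Analysis window (seconds).
#' @export
setClass("SensorSelection",
  representation(peakPairs = "integer", leftPairs = "integer",
                 rightPairs = "integer", windowS = "numeric"))

setValidity("SensorSelection", function(object) {
  if (length(object@leftPairs) != 9 || length(object@rightPairs) != 9)
    return("each hemisphere must contribute 9 pairs")
  if (anyDuplicated(c(object@leftPairs, object@rightPairs)))
    return("left and right selections must be disjoint and unique")
  if (!object@peakPairs["left"] %in% object@leftPairs ||
      !object@peakPairs["right"] %in% object@rightPairs)
    return("peak pairs must belong to their selections")
  TRUE
})

#' Adjacency: sensor neighborhood structure
#'
#' @slot matrix Symmetric, irreflexive logical matrix over the analysed pairs.
#' @slot pairIds Pair ids the rows/columns refer to.
#' @slot thresholdM Linear distance threshold (meters) that defined neighbors.
#' @export
setClass("Adjacency",
  representation(matrix = "matrix", pairIds = "integer",
                 thresholdM = "numeric"))

setValidity("Adjacency", function(object) {
  m <- object@matrix
  if (!is.logical(m) || nrow(m) != ncol(m)) return("need square logical matrix")
  if (any(diag(m))) return("adjacency must be irreflexive")
  if (!isTRUE(all.equal(m, t(m)))) return("adjacency must be symmetric")
  if (any(rowSums(m) == 0)) return("every pair needs at least one neighbor")
  TRUE
})

#' ClusterResult: spatiotemporal cluster permutation test outcome
#'
#' @slot clusters List of clusters; each has `cells` (matrix with columns
#'   `pair`, `time` of sample indices), `sign` (+1/-1) and `sumT`.
#' @slot pValues Monte Carlo (or exact) p-value per cluster, same order.
#' @slot observedMax Named vector `pos`/`neg`: observed per-sign max statistic.
#' @slot nullMax Matrix (nPerm x 2, columns `pos`,`neg`): per-sign null maxima.
#' @slot nPerm Number of permutations used.
#' @slot exhaustive TRUE when all distinct relabelings were enumerated.
#' @slot seed RNG seed.
#' @slot alphaForming Cluster-forming alpha.
#' @slot design `"independent"` or `"dependent"`.
#' @slot info List of test metadata (test name, deviant type, groups, ...).
#' @export
setClass("ClusterResult",
  representation(clusters = "list", pValues = "numeric",
                 observedMax = "numeric", nullMax = "matrix",
                 nPerm = "numeric", exhaustive = "logical", seed = "integer",
                 alphaForming = "numeric", design = "character",
                 info = "list"))

setValidity("ClusterResult", function(object) {
  if (length(object@pValues) != length(object@clusters))
    return("one p-value per cluster required")
  if (length(object@pValues) &&
      (any(object@pValues <= 0) || any(object@pValues > 1)))
    return("p-values must lie in (0, 1]")
  if (nrow(object@nullMax) != object@nPerm)
    return("nullMax must have nPerm rows")
  TRUE
})

#' RejectionReport: artifact rejection summary
#'
#' @slot nTotal,nRejected Trial counts.
#' @slot retainedFraction (nTotal - nRejected) / nTotal.
#' @slot maxZ Per-trial maximum jump z-score.
#' @slot rejected Indices of rejected trials.
#' @export
setClass("RejectionReport",
  representation(nTotal = "numeric", nRejected = "numeric",
                 retainedFraction = "numeric", maxZ = "numeric",
                 rejected = "integer"))

setValidity("RejectionReport", function(object) {
  rf <- (object@nTotal - object@nRejected) / object@nTotal
  if (abs(rf - object@retainedFraction) > 1e-12 ||
      object@retainedFraction < 0 || object@retainedFraction > 1)
    return("retainedFraction inconsistent")
  TRUE
})
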