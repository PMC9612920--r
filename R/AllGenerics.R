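## Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for pipeline objects
#' @description Small accessor layer so user code never touches slots:
#' `waveData()` returns the numeric array/matrix, `samplingRate()` the
#' sampling rate in Hz, `timePoints()` the time axis in seconds relative to
#' stimulus onset, `channelIds()` the channel names, `nPairs()` the number of
#' gradiometer pairs in a layout, `selectedPairs()` the 18 analysed pair ids,
#' and `pValues()` the per-cluster p-values of a test result.
#' @param x An object of one of the package's S4 classes.
#' @return The corresponding component; see Description.
NULL

#' @rdname accessors
#' @export
setGeneric("waveData", function(x) standardGeneric("waveData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))
#' @rdname accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
#' @rdname accessors
#' @export
setGeneric("selectedPairs", function(x) standardGeneric("selectedPairs"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setMethod("waveData", "EpochSet", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("waveData", "Evoked", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("waveData", "MMNmWave", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fsHz)
#' @rdname accessors
#' @export
setMethod("samplingRate", "Evoked", function(x) x@fsHz)
#' @rdname accessors
#' @export
setMethod("samplingRate", "MMNmWave", function(x) x@fsHz)

.timesOf <- function(x) {
  nT <- if (is(x, "EpochSet")) dim(x@data)[3] else ncol(x@data)
  x@t0S + (seq_len(nT) - 1L) / x@fsHz
}
#' @rdname accessors
#' @export
setMethod("timePoints", "EpochSet", .timesOf)
#' @rdname accessors
#' @export
setMethod("timePoints", "Evoked", .timesOf)
#' @rdname accessors
#' @export
setMethod("timePoints", "MMNmWave", .timesOf)

#' @rdname accessors
#' @export
setMethod("channelIds", "EpochSet", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelIds", "Evoked", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelIds", "MMNmWave", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelIds", "SensorLayout", function(x) x@pairs$name)

#' @rdname accessors
#' @export
setMethod("nPairs", "SensorLayout", function(x) nrow(x@pairs))

#' @rdname accessors
#' @export
setMethod("selectedPairs", "SensorSelection",
          function(x) c(x@leftPairs, x@rightPairs))

#' @rdname accessors
#' @export
setMethod("pValues", "ClusterResult", function(x) x@pValues)

#' Subset an EpochSet by trial
#'
#' @param x An [EpochSet-class].
#' @param i Trial indices (numeric or logical).
#' @param j,...,drop Ignored.
#' @return The trial-subset [EpochSet-class].
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, data = x@data[i, , , drop = FALSE],
             condition = x@condition[i],
             analysisStandard = x@analysisStandard[i])
})

setMethod("show", "SensorLayout", function(object) {
  h <- table(object@pairs$hemisphere)
  cat("SensorLayout:", nPairs(object), "gradiometer pairs",
      sprintf("(left %d, right %d, midline %d), radius %.3f m\n",
              h["left"], h["right"],
              if ("midline" %in% names(h)) h[["midline"]] else 0L,
              object@radius))
})

setMethod("show", "BlockSequence", function(object) {
  e <- object@events
  cat(sprintf("BlockSequence '%s' (%s paradigm): %d tones, %d deviants, %.2f s\n",
              object@blockId, object@paradigm, nrow(e),
              sum(e$role == "deviant"),
              max(e$onset_s) + object@soaS))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples (%s, fs %g Hz%s)\n",
              d[1], d[2], d[3],
              if (object@combined) "combined pairs" else "raw gradiometers",
              object@fsHz,
              sprintf(", subject %s/%s/%s", object@subjectId, object@group,
                      object@paradigm)))
  print(table(condition = object@condition))
})

setMethod("show", "Evoked", function(object) {
  cat(sprintf("Evoked [%s]: %d channels x %d samples, %g trials (%s)\n",
              object@condition, nrow(object@data), ncol(object@data),
              object@nTrials,
              if (object@combined) "combined" else "raw"))
})

setMethod("show", "MMNmWave", function(object) {
  cat(sprintf("MMNmWave [%s, %s]: %d pairs x %d samples (subject %s, %s, %s)\n",
              object@deviantType, object@kind, nrow(object@data),
              ncol(object@data), object@subjectId, object@group,
              object@paradigm))
})

setMethod("show", "SensorSelection", function(object) {
  cat(sprintf("SensorSelection: 2 x 9 pairs, peaks L=%d R=%d, window %g-%g s\n",
              object@peakPairs["left"], object@peakPairs["right"],
              object@windowS[1], object@windowS[2]))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult (%s design, %s%d permutations, seed %d)\n",
              object@design, if (object@exhaustive) "exhaustive, " else "",
              object@nPerm, object@seed))
  if (length(object@clusters) == 0) {
    cat("  no clusters\n")
  } else {
    df <- clusterTable(object)
    print(df, row.names = FALSE)
  }
})

setMethod("show", "RejectionReport", function(object) {
  cat(sprintf("RejectionReport: %d/%d trials retained (%.1f%%)\n",
              object@nTotal - object@nRejected, object@nTotal,
              100 * object@retainedFraction))
})

#' Tabulate clusters of a permutation test
#'
#' @param x A [ClusterResult-class].
#' @return data.frame with one row per cluster: sign, size, summed t and p.
#' @export
clusterTable <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  if (length(x@clusters) == 0)
    return(data.frame(sign = integer(0), nCells = integer(0),
                      sumT = numeric(0), p = numeric(0)))
  data.frame(
    sign = vapply(x@clusters, function(cl) cl$sign, numeric(1)),
    nCells = vapply(x@clusters, function(cl) nrow(cl$cells), integer(1)),
    sumT = vapply(x@clusters, function(cl) cl$sumT, numeric(1)),
    p = x@pValues)
}
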