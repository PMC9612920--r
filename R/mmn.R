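## Empirical and modeled mismatch difference waves, grand averaging,
## peak-sensor and analysis-window selection.

.checkSameAxes <- function(a, b) {
  if (!identical(dim(waveData(a)), dim(waveData(b))) ||
      !identical(channelIds(a), channelIds(b)) ||
      abs(a@fsHz - b@fsHz) > 1e-9 || abs(a@t0S - b@t0S) > 1e-9)
    stop("axis mismatch between waves")
}

#' Empirical mismatch wave
#'
#' `deviant average - standard average` on the combined-gradiometer scale,
#' for one subject and paradigm.
#'
#' @param dev Combined [Evoked-class] of a deviant condition.
#' @param std Combined [Evoked-class] of the standard condition.
#' @return An [MMNmWave-class] of kind `"empirical"`.
#' @export
empiricalMMNm <- function(dev, std) {
  stopifnot(is(dev, "Evoked"), is(std, "Evoked"))
  if (std@condition != "STD") stop("std must be the standard condition")
  if (dev@condition == "STD") stop("dev must be a deviant condition")
  if (dev@subjectId != std@subjectId || dev@paradigm != std@paradigm)
    stop("dev and std must come from the same subject and paradigm")
  .checkSameAxes(dev, std)
  methods::new("MMNmWave", data = dev@data - std@data,
               deviantType = dev@condition, kind = "empirical",
               nTrialsDeviant = dev@nTrials, nTrialsStandard = std@nTrials,
               channelNames = dev@channelNames, fsHz = dev@fsHz,
               t0S = dev@t0S, subjectId = dev@subjectId, group = dev@group,
               paradigm = dev@paradigm)
}

#' Modeled mismatch wave (additive model)
#'
#' The linear additive-model prediction for a double or triple deviant: the
#' element-wise sum of the empirical mismatch waves of the constituent
#' single-feature deviants.
#'
#' @param singles List of 2 or 3 empirical single-deviant
#'   [MMNmWave-class] objects of the same subject and paradigm, with
#'   disjoint singleton constituents.
#' @return An [MMNmWave-class] of kind `"modeled"`.
#' @export
modeledMMNm <- function(singles) {
  stopifnot(length(singles) %in% c(2, 3))
  types <- vapply(singles, function(w) w@deviantType, "")
  if (!all(types %in% c("F", "I", "L")) || anyDuplicated(types))
    stop("singles must be distinct single-feature waves")
  if (!all(vapply(singles, function(w) w@kind, "") == "empirical"))
    stop("singles must be empirical waves")
  for (w in singles[-1]) {
    .checkSameAxes(singles[[1]], w)
    if (w@subjectId != singles[[1]]@subjectId ||
        w@paradigm != singles[[1]]@paradigm)
      stop("singles must share subject and paradigm")
  }
  dat <- Reduce(`+`, lapply(singles, waveData))
  methods::new("MMNmWave", data = dat,
               deviantType = .constituentsToCode(types), kind = "modeled",
               nTrialsDeviant = sum(vapply(singles,
                                           function(w) w@nTrialsDeviant, 0)),
               nTrialsStandard = singles[[1]]@nTrialsStandard,
               channelNames = singles[[1]]@channelNames,
               fsHz = singles[[1]]@fsHz, t0S = singles[[1]]@t0S,
               subjectId = singles[[1]]@subjectId,
               group = singles[[1]]@group,
               paradigm = singles[[1]]@paradigm)
}

#' Empirical-minus-modeled additivity difference
#'
#' Negative values indicate subadditivity (the empirical response falls
#' short of the additive prediction) on the combined-RMS scale.
#'
#' @param empirical,modeled [MMNmWave-class] objects of the same deviant
#'   type and subject, one empirical and one modeled.
#' @return Numeric matrix, channels x time.
#' @export
additivityDifference <- function(empirical, modeled) {
  stopifnot(is(empirical, "MMNmWave"), is(modeled, "MMNmWave"))
  if (empirical@deviantType != modeled@deviantType)
    stop("deviant types differ")
  if (empirical@subjectId != modeled@subjectId)
    stop("subjects differ")
  if (empirical@kind == modeled@kind) stop("kinds must differ")
  .checkSameAxes(empirical, modeled)
  waveData(empirical) - waveData(modeled)
}

#' Grand average of waves
#'
#' Unweighted mean over a list of [Evoked-class] or [MMNmWave-class]
#' objects (equal weight per element). Metadata fields that differ across
#' elements are pooled (`"all"` / `"MIX"` / `"mixed"`).
#'
#' @param waves Nonempty list with identical axes.
#' @return An object of the same class as the inputs.
#' @export
grandAverage <- function(waves) {
  stopifnot(length(waves) >= 1)
  for (w in waves[-1]) .checkSameAxes(waves[[1]], w)
  dat <- Reduce(`+`, lapply(waves, waveData)) / length(waves)
  proto <- waves[[1]]
  pool <- function(field, mixed) {
    vals <- unique(vapply(waves, function(w) methods::slot(w, field), ""))
    if (length(vals) == 1) vals else mixed
  }
  if (is(proto, "MMNmWave")) {
    methods::new("MMNmWave", data = dat,
                 deviantType = pool("deviantType", "MIX"),
                 kind = pool("kind", "mixed"),
                 nTrialsDeviant = mean(vapply(waves,
                   function(w) w@nTrialsDeviant, 0)),
                 nTrialsStandard = mean(vapply(waves,
                   function(w) w@nTrialsStandard, 0)),
                 channelNames = proto@channelNames, fsHz = proto@fsHz,
                 t0S = proto@t0S, subjectId = pool("subjectId", "all"),
                 group = pool("group", "all"),
                 paradigm = pool("paradigm", "all"))
  } else {
    initialize(proto, data = dat,
               nTrials = mean(vapply(waves, function(w) w@nTrials, 0)),
               subjectId = pool("subjectId", "all"),
               group = pool("group", "all"),
               paradigm = pool("paradigm", "all"))
  }
}

#' Select peak sensors and neighborhoods
#'
#' Per hemisphere, finds the combined-gradiometer pair with the maximum
#' grand-average mismatch amplitude inside the analysis window, then adds
#' its 8 nearest same-hemisphere pairs by 3-D Euclidean distance, for a
#' total of 2 x 9 = 18 pairs. The combined signal is non-negative, so the
#' peak search needs no polarity handling. Ties are broken by the lowest
#' pair id; midline pairs are never selected.
#'
#' @param grand Grand-average [MMNmWave-class] (or combined channels x time
#'   matrix with pair rownames).
#' @param layout The [SensorLayout-class].
#' @param windowS Analysis window (default 100-300 ms).
#' @return A [SensorSelection-class].
#' @export
selectPeakSensors <- function(grand, layout, windowS = c(0.100, 0.300)) {
  dat <- if (is(grand, "MMNmWave")) waveData(grand) else grand
  chn <- if (is(grand, "MMNmWave")) channelIds(grand) else rownames(grand)
  times <- if (is(grand, "MMNmWave")) timePoints(grand) else
    as.numeric(colnames(grand))
  widx <- windowIndices(times, windowS)
  p <- layout@pairs
  rowOf <- match(p$name, chn)
  if (anyNA(rowOf)) stop("layout pairs missing from the wave")
  sel <- lapply(c("left", "right"), function(h) {
    hp <- which(p$hemisphere == h)
    if (length(hp) < 9)
      stop("fewer than 9 pairs in the ", h, " hemisphere")
    peakVal <- apply(dat[rowOf[hp], widx, drop = FALSE], 1, max)
    peak <- hp[order(-peakVal, p$pair_id[hp])[1]]
    d <- sqrt((p$x[hp] - p$x[peak])^2 + (p$y[hp] - p$y[peak])^2 +
                (p$z[hp] - p$z[peak])^2)
    nb <- hp[order(d, p$pair_id[hp])]
    nine <- nb[1:9]                       # peak itself has d = 0
    list(peak = p$pair_id[peak], pairs = as.integer(p$pair_id[nine]))
  })
  methods::new("SensorSelection",
               peakPairs = c(left = as.integer(sel[[1]]$peak),
                             right = as.integer(sel[[2]]$peak)),
               leftPairs = sel[[1]]$pairs, rightPairs = sel[[2]]$pairs,
               windowS = windowS)
}

#' Peak latency of the selected sensors
#'
#' Argmax, over the analysis window, of the mean across the selected pairs.
#' Invariant to global positive scaling.
#'
#' @param grand Grand-average [MMNmWave-class].
#' @param selection A [SensorSelection-class].
#' @param layout The [SensorLayout-class] (to map pair ids to rows).
#' @return Peak latency in seconds.
#' @export
peakLatency <- function(grand, selection, layout) {
  rows <- match(layout@pairs$name[match(selectedPairs(selection),
                                        layout@pairs$pair_id)],
                channelIds(grand))
  times <- timePoints(grand)
  widx <- windowIndices(times, selection@windowS)
  avg <- colMeans(waveData(grand)[rows, widx, drop = FALSE])
  times[widx[which.max(avg)]]
}
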