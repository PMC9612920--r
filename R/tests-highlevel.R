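## Study-level hypothesis tests: MMNm presence, deviant-ordering validity
## checks, additivity-by-expertise interaction, and within-group simple
## effects of additivity. All operate on the selected 2 x 9 combined pairs
## within the 100-300 ms analysis window.

## Extract a wave's selection x window map (rows ordered as the selection).
.extractMap <- function(w, selection, layout, windowS) {
  pnames <- layout@pairs$name[match(selectedPairs(selection),
                                    layout@pairs$pair_id)]
  rows <- match(pnames, channelIds(w))
  if (anyNA(rows)) stop("selected pairs missing from wave channels")
  widx <- windowIndices(timePoints(w), windowS)
  waveData(w)[rows, widx, drop = FALSE]
}

## Like .extractMap, but also accepts uncombined waves, taking both raw
## channels of every selected pair.
.extractMapAny <- function(w, selection, layout, windowS) {
  pnames <- layout@pairs$name[match(selectedPairs(selection),
                                    layout@pairs$pair_id)]
  chn <- channelIds(w)
  if (all(pnames %in% chn)) return(.extractMap(w, selection, layout, windowS))
  rawNames <- as.vector(rbind(paste0(pnames, "a"), paste0(pnames, "b")))
  rows <- match(rawNames, chn)
  if (anyNA(rows)) stop("selected pairs missing from wave channels")
  widx <- windowIndices(timePoints(w), windowS)
  waveData(w)[rows, widx, drop = FALSE]
}

## Stack a list of per-subject maps into a subjects x pairs x time array.
.stackMaps <- function(maps) {
  arr <- array(0, c(length(maps), nrow(maps[[1]]), ncol(maps[[1]])))
  for (i in seq_along(maps)) arr[i, , ] <- maps[[i]]
  arr
}

.wavesField <- function(waves, field) vapply(waves, methods::slot, "", name = field)

## Per-subject empirical-minus-modeled difference maps for one deviant type.
.additivityMaps <- function(waves, deviantType, selection, layout, windowS,
                            group = NULL) {
  kinds <- .wavesField(waves, "kind")
  types <- .wavesField(waves, "deviantType")
  grp <- .wavesField(waves, "group")
  pick <- types == deviantType
  if (!is.null(group)) pick <- pick & grp == group
  emp <- waves[pick & kinds == "empirical"]
  mod <- waves[pick & kinds == "modeled"]
  es <- .wavesField(emp, "subjectId")
  ms <- .wavesField(mod, "subjectId")
  common <- intersect(es, ms)
  if (length(common) == 0) stop("no subjects with both empirical and modeled waves")
  maps <- lapply(common, function(s) {
    d <- additivityDifference(emp[[match(s, es)]], mod[[match(s, ms)]])
    w <- emp[[match(s, es)]]
    widx <- windowIndices(timePoints(w), windowS)
    pnames <- layout@pairs$name[match(selectedPairs(selection),
                                      layout@pairs$pair_id)]
    d[match(pnames, channelIds(w)), widx, drop = FALSE]
  })
  list(maps = maps, subjects = common,
       groups = grp[pick & kinds == "empirical"][match(common, es)])
}

#' Additivity-by-expertise interaction test
#'
#' Computes each subject's empirical-minus-modeled mismatch difference for
#' one double/triple deviant and compares the two groups with an
#' independent-design cluster permutation test over the selected sensors
#' and window. A significant (typically negative) cluster indicates that
#' subadditivity differs between groups.
#'
#' @param waves Flat list of [MMNmWave-class] objects (both kinds, both
#'   groups).
#' @param deviantType One of `"FI"`, `"IL"`, `"LF"`, `"FIL"`.
#' @param layout,selection Sensor geometry and the 2 x 9 selection.
#' @param spec A [testSpec()] with `design = "independent"`; its
#'   `alphaInference` is typically [bonferroniAlpha()] = 0.00625.
#' @param groups Optional explicit group ordering (group 1 vs group 2).
#' @return A [ClusterResult-class].
#' @export
interactionTest <- function(waves, deviantType, layout, selection, spec,
                            groups = NULL) {
  stopifnot(length(deviantConstituents(deviantType)) >= 2)
  am <- .additivityMaps(waves, deviantType, selection, layout, spec$windowS)
  if (is.null(groups)) groups <- unique(am$groups)
  stopifnot(length(groups) == 2)
  a <- .stackMaps(am$maps[am$groups == groups[1]])
  b <- .stackMaps(am$maps[am$groups == groups[2]])
  adjacency <- buildAdjacency(layout, selection)
  spec$design <- "independent"
  permutationTest(a, b, spec, adjacency,
                  info = list(test = "interaction", deviantType = deviantType,
                              groups = groups))
}

#' Simple effect of additivity within one group
#'
#' Dependent-design cluster permutation test of empirical vs. modeled
#' mismatch waves (per-subject paired differences) within a single group;
#' run as a follow-up when the additivity-by-expertise interaction is
#' significant.
#'
#' @inheritParams interactionTest
#' @param group Group label.
#' @return A [ClusterResult-class].
#' @export
simpleEffectTest <- function(waves, deviantType, group, layout, selection,
                             spec) {
  am <- .additivityMaps(waves, deviantType, selection, layout, spec$windowS,
                        group = group)
  spec$design <- "dependent"
  adjacency <- buildAdjacency(layout, selection)
  permutationTest(.stackMaps(am$maps), spec = spec, adjacency = adjacency,
                  info = list(test = "simple_effect",
                              deviantType = deviantType, group = group))
}

#' MMNm presence test
#'
#' Dependent-design cluster permutation test of deviant vs. standard evoked
#' responses within one group: establishes whether a mismatch response is
#' present in the 100-300 ms window.
#'
#' @param evokeds Flat list of combined [Evoked-class] objects (all
#'   conditions, one or more subjects).
#' @inheritParams interactionTest
#' @param group Group label.
#' @return A [ClusterResult-class].
#' @export
presenceTest <- function(evokeds, deviantType, group, layout, selection,
                         spec) {
  conds <- vapply(evokeds, function(e) e@condition, "")
  grps <- vapply(evokeds, function(e) e@group, "")
  dv <- evokeds[conds == deviantType & grps == group]
  st <- evokeds[conds == "STD" & grps == group]
  ds <- vapply(dv, function(e) e@subjectId, "")
  ss <- vapply(st, function(e) e@subjectId, "")
  common <- intersect(ds, ss)
  if (length(common) < 2) stop("need >= 2 subjects with deviant and standard")
  maps <- lapply(common, function(s) {
    .extractMap(dv[[match(s, ds)]], selection, layout, spec$windowS) -
      .extractMap(st[[match(s, ss)]], selection, layout, spec$windowS)
  })
  spec$design <- "dependent"
  adjacency <- buildAdjacency(layout, selection)
  permutationTest(.stackMaps(maps), spec = spec, adjacency = adjacency,
                  info = list(test = "presence", deviantType = deviantType,
                              group = group))
}

#' The nine ordering comparisons
#'
#' Pairwise validity checks that mismatch responses grow with the number of
#' deviating features: triple vs. each double, and each double vs. its
#' constituent singles.
#'
#' @return data.frame with columns `larger`, `smaller`.
#' @export
orderingComparisons <- function() {
  data.frame(
    larger = c("FIL", "FIL", "FIL", "FI", "FI", "IL", "IL", "LF", "LF"),
    smaller = c("FI", "IL", "LF", "F", "I", "I", "L", "L", "F"))
}

#' Deviant-ordering validity test
#'
#' Dependent-design cluster permutation test that the empirical mismatch
#' wave of the higher-order deviant exceeds that of the lower-order one,
#' across all subjects regardless of group. Evaluated directionally
#' (positive tail) by default; no multiple-comparison correction is applied
#' to these secondary validity checks.
#'
#' @inheritParams interactionTest
#' @param larger,smaller Deviant codes (e.g. `"FIL"` vs `"FI"`).
#' @param tail `"pos"` (one-sided, default) or `"both"`.
#' @return A [ClusterResult-class].
#' @export
orderingTest <- function(waves, larger, smaller, layout, selection, spec,
                         tail = "pos") {
  kinds <- .wavesField(waves, "kind")
  types <- .wavesField(waves, "deviantType")
  hi <- waves[kinds == "empirical" & types == larger]
  lo <- waves[kinds == "empirical" & types == smaller]
  hs <- .wavesField(hi, "subjectId")
  ls <- .wavesField(lo, "subjectId")
  common <- intersect(hs, ls)
  if (length(common) < 2) stop("need >= 2 subjects with both deviants")
  maps <- lapply(common, function(s) {
    .extractMap(hi[[match(s, hs)]], selection, layout, spec$windowS) -
      .extractMap(lo[[match(s, ls)]], selection, layout, spec$windowS)
  })
  spec$design <- "dependent"
  spec$tail <- tail
  adjacency <- buildAdjacency(layout, selection)
  permutationTest(.stackMaps(maps), spec = spec, adjacency = adjacency,
                  info = list(test = "ordering", larger = larger,
                              smaller = smaller))
}
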