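## Oddball block construction: complex musical multi-feature paradigm
## (Alberti-bass patterns, SOA 205 ms) and simple control paradigm
## (classical oddball, SOA 400 ms).

.NOTE_BASE <- c(C = 0, D = 2, E = 4, F = 5, G = 7, A = 9, B = 11)

## "A#2" -> MIDI number (A4 = 69)
.noteToMidi <- function(note) {
  m <- regmatches(note, regexec("^([A-Ga-g])([#b]?)(-?[0-9]+)$", note))[[1]]
  if (length(m) == 0) stop("unparseable note name: ", note)
  base <- .NOTE_BASE[toupper(m[2])]
  acc <- switch(m[3], "#" = 1L, "b" = -1L, 0L)
  octave <- as.integer(m[4])
  unname(12L * (octave + 1L) + base + acc)
}

.midiToHz <- function(midi, tuningA4Hz = 440) tuningA4Hz * 2^((midi - 69) / 12)

#' Equal-temperament chromatic scale frequencies
#'
#' Fundamental frequencies of every semitone from `lowNote` to `highNote`
#' under twelve-tone equal temperament, f = tuning * 2^(semitones from A4 /
#' 12), rounded to 0.01 Hz for reporting. The default standard-tone range of
#' the paradigms, A#2-A3, yields 12 values from 116.54 to 220.00 Hz.
#'
#' @param lowNote,highNote Scientific pitch notation (e.g. `"A#2"`, `"A3"`);
#'   A4 is MIDI 69.
#' @param tuningA4Hz Tuning reference for A4 in Hz (default 440).
#' @return Numeric vector of frequencies in Hz, one per semitone.
#' @examples
#' chromaticFrequencies("A#2", "A3")
#' @export
chromaticFrequencies <- function(lowNote = "A#2", highNote = "A3",
                                 tuningA4Hz = 440) {
  stopifnot(tuningA4Hz > 0)
  lo <- .noteToMidi(lowNote)
  hi <- .noteToMidi(highNote)
  if (lo > hi) stop("lowNote must not be above highNote")
  round(.midiToHz(lo:hi, tuningA4Hz), 2)
}

#' Shift a frequency by a number of cents
#'
#' @param f0 Frequency in Hz (> 0).
#' @param cents Signed shift in cents (100 cents = 1 semitone); the paradigm's
#'   frequency deviant uses -35 cents.
#' @return `f0 * 2^(cents / 1200)`.
#' @examples
#' centsShift(220, -35)
#' @export
centsShift <- function(f0, cents) {
  stopifnot(all(f0 > 0))
  f0 * 2^(cents / 1200)
}

## Shuffled pitch-level orders for `nIter` iterations of the 12 chromatic
## levels, avoiding a repeat of the same level across iteration boundaries.
.pitchOrders <- function(nIter, nLevels = 12L) {
  out <- vector("list", nIter)
  prevLast <- -1L
  for (i in seq_len(nIter)) {
    repeat {
      ord <- sample.int(nLevels) - 1L
      if (ord[1] != prevLast) break
    }
    out[[i]] <- ord
    prevLast <- ord[nLevels]
  }
  out
}

## Alberti bass: lowest-highest-middle-highest, rendered as major-triad
## semitone offsets from the pattern's root.
.ALBERTI_OFFSETS <- c(0L, 7L, 4L, 7L)

.emptyEvents <- function(n) {
  data.frame(index = seq_len(n), onset_s = NA_real_,
             role = NA_character_, deviant_type = NA_character_,
             pitch_index = NA_integer_, pitch_hz = NA_real_,
             pattern_position = NA_integer_, pattern_id = NA_integer_,
             is_analysis_standard = FALSE)
}

#' Generate one block of the complex musical multi-feature paradigm
#'
#' One block comprises three iterations of the 12 chromatic pitch levels
#' (A#2-A3). At each pitch level the seven deviant types occur once, in a
#' seeded pseudo-random permutation; each deviant slot consists of three
#' standard Alberti-bass patterns followed by one pattern whose third tone is
#' the deviant. All tones are presented at a constant SOA of 205 ms, so a
#' block holds 3 x 12 x 7 x 4 patterns x 4 tones = 4032 tones (826.56 s),
#' with each deviant type occurring 36 times per block (144 across 4 blocks).
#'
#' @param blockId Block identifier string.
#' @param seed Integer seed; the same seed reproduces the block exactly.
#' @param soaS Stimulus onset asynchrony in seconds (default 0.205).
#' @param tuningA4Hz Tuning reference (Hz).
#' @return A [BlockSequence-class].
#' @examples
#' b <- generateComplexBlock("M1", seed = 1)
#' table(b@events$deviant_type[b@events$role == "deviant"])
#' @export
generateComplexBlock <- function(blockId, seed, soaS = 0.205,
                                 tuningA4Hz = 440) {
  freqs <- chromaticFrequencies("A#2", "A3", tuningA4Hz)
  rootMidi <- .noteToMidi("A#2") + (0:11)
  withSeed(seed, {
    pitchOrders <- .pitchOrders(3L)
    devOrders <- replicate(3L * 12L, sample(deviantTypes()), simplify = FALSE)
    nTones <- 3L * 12L * 7L * 4L * 4L
    ev <- .emptyEvents(nTones)
    row <- 1L; patId <- 0L; slot <- 0L
    for (it in 1:3) for (lv in pitchOrders[[it]]) {
      slot <- slot + 1L
      devOrder <- devOrders[[slot]]
      for (dv in devOrder) {
        for (pat in 1:4) {             # 3 standard patterns + 1 deviant pattern
          patId <- patId + 1L
          for (pos in 1:4) {
            isDev <- (pat == 4L && pos == 3L)
            ev$role[row] <- if (isDev) "deviant" else "standard"
            ev$deviant_type[row] <- if (isDev) dv else "STD"
            ev$pitch_index[row] <- lv
            toneHz <- .midiToHz(rootMidi[lv + 1L] + .ALBERTI_OFFSETS[pos],
                                tuningA4Hz)
            if (isDev && "F" %in% deviantConstituents(dv))
              toneHz <- centsShift(toneHz, -35)
            ev$pitch_hz[row] <- round(toneHz, 2)
            ev$pattern_position[row] <- pos
            ev$pattern_id[row] <- patId
            row <- row + 1L
          }
        }
      }
    }
    ev$onset_s <- (ev$index - 1L) * soaS
    methods::new("BlockSequence", paradigm = "complex", blockId = blockId,
                 events = ev, soaS = soaS, seed = as.integer(seed))
  })
}

#' Generate one block of the simple control paradigm
#'
#' A classical oddball sequence at a constant SOA of 400 ms: four iterations
#' of the 12 chromatic pitch levels, with the seven deviant types occurring
#' once per pitch level in seeded pseudo-random order, each deviant preceded
#' by 3-5 standards drawn uniformly at random. Each deviant type occurs
#' 4 x 12 = 48 times per block (144 across 3 blocks); expected block duration
#' is 7 x 12 x 4 x 5 x 0.4 s = 672 s (about 11 min).
#'
#' @inheritParams generateComplexBlock
#' @param soaS Stimulus onset asynchrony in seconds (default 0.400).
#' @return A [BlockSequence-class].
#' @export
generateSimpleBlock <- function(blockId, seed, soaS = 0.400,
                                tuningA4Hz = 440) {
  rootMidi <- .noteToMidi("A#2") + (0:11)
  withSeed(seed, {
    pitchOrders <- .pitchOrders(4L)
    rows <- list(); k <- 0L
    for (it in 1:4) for (lv in pitchOrders[[it]]) {
      for (dv in sample(deviantTypes())) {
        nStd <- sample(3:5, 1L)
        toneHz <- .midiToHz(rootMidi[lv + 1L], tuningA4Hz)
        devHz <- if ("F" %in% deviantConstituents(dv))
          centsShift(toneHz, -35) else toneHz
        k <- k + 1L
        rows[[k]] <- data.frame(
          role = c(rep("standard", nStd), "deviant"),
          deviant_type = c(rep("STD", nStd), dv),
          pitch_index = lv,
          pitch_hz = round(c(rep(toneHz, nStd), devHz), 2))
      }
    }
    evc <- do.call(rbind, rows)
    n <- nrow(evc)
    ev <- .emptyEvents(n)
    ev$role <- evc$role
    ev$deviant_type <- evc$deviant_type
    ev$pitch_index <- evc$pitch_index
    ev$pitch_hz <- evc$pitch_hz
    ev$onset_s <- (ev$index - 1L) * soaS
    methods::new("BlockSequence", paradigm = "simple", blockId = blockId,
                 events = ev, soaS = soaS, seed = as.integer(seed))
  })
}

#' Mark analysis standards
#'
#' Flags the standard trials retained for analysis: for both paradigms, only
#' the third occurrence of the standard tone after each deviant enters the
#' standard condition. In the complex paradigm this is the tone at pattern
#' position 3 (the position deviants occupy) of the third standard pattern
#' following each deviant pattern, so that standard and deviant trials share
#' within-pattern context. A deviant with fewer than three trailing standards
#' before the block end contributes no standard trial.
#'
#' @param seq A [BlockSequence-class].
#' @return The sequence with `is_analysis_standard` filled in.
#' @export
markAnalysisStandards <- function(seq) {
  stopifnot(is(seq, "BlockSequence"))
  ev <- seq@events
  ev$is_analysis_standard <- FALSE
  devIdx <- which(ev$role == "deviant")
  if (length(devIdx) == 0) {
    warning("sequence contains no deviants; nothing to mark")
    return(seq)
  }
  if (seq@paradigm == "simple") {
    stdPos <- which(ev$role == "standard")
    for (d in devIdx) {
      trailing <- stdPos[stdPos > d]
      if (length(trailing) >= 3) ev$is_analysis_standard[trailing[3]] <- TRUE
    }
  } else {
    ## pattern-level rule: 3rd standard pattern after each deviant pattern
    devPats <- unique(ev$pattern_id[devIdx])
    patIsStd <- tapply(ev$role == "standard", ev$pattern_id, all)
    stdPats <- as.integer(names(patIsStd))[patIsStd]
    for (p in devPats) {
      trailing <- stdPats[stdPats > p]
      if (length(trailing) >= 3) {
        target <- which(ev$pattern_id == trailing[3] &
                          ev$pattern_position == 3L)
        ev$is_analysis_standard[target] <- TRUE
      }
    }
  }
  initialize(seq, events = ev)
}

#' Summarize blocks into a trial table
#'
#' Per paradigm and condition: deviant trial count, analysis-standard count,
#' and total presentation time.
#'
#' @param blocks List of [BlockSequence-class] objects.
#' @return data.frame with columns `paradigm`, `condition`, `n_deviants`,
#'   `n_analysis_standards`, `total_duration_s`.
#' @export
paradigmTrialTable <- function(blocks) {
  stopifnot(length(blocks) > 0)
  rows <- lapply(split(blocks, vapply(blocks, function(b) b@paradigm, "")),
    function(bs) {
      ev <- do.call(rbind, lapply(bs, function(b) b@events))
      dur <- sum(vapply(bs, function(b) max(b@events$onset_s) + b@soaS, 0))
      nStd <- sum(ev$is_analysis_standard)
      devs <- ev[ev$role == "deviant", ]
      cond <- c("STD", deviantTypes())
      data.frame(paradigm = bs[[1]]@paradigm, condition = cond,
                 n_deviants = c(0L, vapply(deviantTypes(), function(dv)
                   sum(devs$deviant_type == dv), 0L)),
                 n_analysis_standards = c(nStd, rep(0L, 7)),
                 total_duration_s = dur, row.names = NULL)
    })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write or read an event log
#'
#' Tab-separated event logs with one row per tone.
#'
#' @param blocks List of [BlockSequence-class] objects.
#' @param path Output TSV path.
#' @return `writeEventLog` returns `path` invisibly; `readEventLog` a
#'   data.frame.
#' @export
writeEventLog <- function(blocks, path) {
  ev <- do.call(rbind, lapply(blocks, function(b) {
    cbind(block_id = b@blockId, paradigm = b@paradigm, b@events)
  }))
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEventLog
#' @export
readEventLog <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
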