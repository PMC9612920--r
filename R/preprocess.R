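## Epoch cleaning chain: SQUID-jump rejection, zero-phase Butterworth
## band-pass, planar RMS combination, baseline correction, averaging.
## Stage order is fixed: reject -> filter -> combine -> baseline -> average.

#' Reject trials containing SQUID-like jumps
#'
#' Per channel, the absolute first difference of each trial's time series is
#' z-scored against that channel's pooled (all trials x samples) mean and SD
#' of absolute first differences; a trial is rejected when its maximum z over
#' channels and samples exceeds `zCutoff`. Sensitive to steps, insensitive
#' to slow evoked components.
#'
#' @param epochs An uncombined [EpochSet-class].
#' @param zCutoff Rejection threshold (default 30).
#' @return List with `epochs` (retained trials) and `report`
#'   (a [RejectionReport-class]).
#' @export
rejectJumps <- function(epochs, zCutoff = 30) {
  stopifnot(is(epochs, "EpochSet"))
  if (epochs@combined) stop("rejectJumps expects uncombined raw pairs")
  d <- dim(epochs@data)
  dif <- abs(epochs@data[, , -1, drop = FALSE] -
               epochs@data[, , -d[3], drop = FALSE])
  nPer <- d[1] * (d[3] - 1)
  mu <- apply(dif, 2, mean)
  sdv <- sqrt(pmax(apply(dif, 2, function(x) sum((x - mean(x))^2)) /
                     (nPer - 1), 0))
  maxZ <- numeric(d[1])
  for (ch in seq_len(d[2])) {
    if (sdv[ch] < 1e-12) next
    z <- (dif[, ch, ] - mu[ch]) / sdv[ch]
    maxZ <- pmax(maxZ, apply(z, 1, max))
  }
  rej <- which(maxZ > zCutoff)
  if (length(rej) == d[1])
    stop("all trials rejected; review the z cutoff")
  report <- methods::new("RejectionReport", nTotal = d[1],
                         nRejected = length(rej),
                         retainedFraction = (d[1] - length(rej)) / d[1],
                         maxZ = maxZ, rejected = as.integer(rej))
  keep <- if (length(rej)) -rej else seq_len(d[1])
  list(epochs = epochs[keep], report = report)
}

## Squared magnitude response of a two-pass digital Butterworth band-pass
## at the n FFT bin frequencies.
.butterGain2 <- function(order, lowHz, highHz, fsHz, n) {
  bf <- signal::butter(order, c(lowHz, highHz) / (fsHz / 2), type = "pass")
  w <- 2 * pi * (seq_len(n) - 1) / n
  num <- exp(-1i * outer(w, seq_along(bf$b) - 1)) %*% bf$b
  den <- exp(-1i * outer(w, seq_along(bf$a) - 1)) %*% bf$a
  as.vector(Mod(num / den)^2)
}

## Indices implementing symmetric (mirror) padding of a length-n series
## out to length nPad.
.mirrorIndices <- function(n, nPad) {
  nL <- (nPad - n) %/% 2
  p <- (1 - nL):(nPad - nL)
  if (n == 1) return(rep(1L, nPad))
  period <- 2L * n - 2L
  q <- (p - 1) %% period
  ifelse(q < n, q + 1, 2L * n - 1L - q)
}

## Zero-phase band-pass of a time x series matrix via the two-pass
## Butterworth squared magnitude response applied in the frequency domain
## on mirror-padded data.
.bandpassMatrix <- function(X, fsHz, lowHz, highHz, order, padS,
                            chunk = 4096L) {
  n <- nrow(X)
  nPad <- max(n, round(padS * fsHz))
  idx <- .mirrorIndices(n, nPad)
  nL <- (nPad - n) %/% 2
  keep <- nL + seq_len(n)
  g <- .butterGain2(order, lowHz, highHz, fsHz, nPad)
  out <- X
  for (st in seq(1, ncol(X), by = chunk)) {
    cols <- st:min(st + chunk - 1L, ncol(X))
    Xp <- X[idx, cols, drop = FALSE]
    Y <- Re(stats::mvfft(stats::mvfft(Xp) * g, inverse = TRUE)) / nPad
    out[, cols] <- Y[keep, , drop = FALSE]
  }
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Two-pass (forward-backward, hence zero-phase) digital Butterworth
#' band-pass, order `order` per pass, applied per trial and channel after
#' symmetric mirror padding of each epoch to `padS` seconds to avoid filter
#' edge artifacts. Output length is unchanged. The two-pass response is
#' realised as the squared magnitude response applied in the frequency
#' domain of the padded series.
#'
#' @param x An [EpochSet-class], [Evoked-class], or channels x time matrix.
#' @param lowHz,highHz Band edges in Hz (defaults 1 and 40);
#'   `highHz` must be below the Nyquist frequency.
#' @param order Butterworth order per pass (default 4).
#' @param padS Total padded length in seconds (default 3).
#' @param fsHz Sampling rate; taken from the object when available.
#' @return Filtered object of the same type.
#' @export
setGeneric("bandpass", function(x, lowHz = 1, highHz = 40, order = 4,
                                padS = 3, fsHz = NULL)
  standardGeneric("bandpass"))

.checkBand <- function(lowHz, highHz, fsHz) {
  if (lowHz >= highHz) stop("lowHz must be below highHz")
  if (highHz >= fsHz / 2) stop("highHz must be below the Nyquist frequency")
}

#' @rdname bandpass
#' @export
setMethod("bandpass", "EpochSet", function(x, lowHz, highHz, order, padS,
                                           fsHz) {
  .checkBand(lowHz, highHz, x@fsHz)
  d <- dim(x@data)
  M <- matrix(aperm(x@data, c(3, 1, 2)), nrow = d[3])  # time x (trial*chan)
  M <- .bandpassMatrix(M, x@fsHz, lowHz, highHz, order, padS)
  x@data <- aperm(array(M, c(d[3], d[1], d[2])), c(2, 3, 1))
  x
})

#' @rdname bandpass
#' @export
setMethod("bandpass", "Evoked", function(x, lowHz, highHz, order, padS,
                                         fsHz) {
  .checkBand(lowHz, highHz, x@fsHz)
  x@data <- t(.bandpassMatrix(t(x@data), x@fsHz, lowHz, highHz, order, padS))
  x
})

#' @rdname bandpass
#' @export
setMethod("bandpass", "matrix", function(x, lowHz, highHz, order, padS,
                                         fsHz) {
  if (is.null(fsHz)) stop("fsHz required for matrix input")
  .checkBand(lowHz, highHz, fsHz)
  t(.bandpassMatrix(t(x), fsHz, lowHz, highHz, order, padS))
})

## Map interleaved raw channel names ("P001a"/"P001b") to pair structure.
.pairIndex <- function(channelNames) {
  stem <- sub("[ab]$", "", channelNames)
  suffix <- substring(channelNames, nchar(channelNames))
  pairs <- unique(stem)
  ia <- match(paste0(pairs, "a"), channelNames)
  ib <- match(paste0(pairs, "b"), channelNames)
  bad <- is.na(ia) | is.na(ib)
  if (any(bad))
    stop("unpaired channel(s): ", paste(pairs[bad], collapse = ", "))
  if (!all(suffix %in% c("a", "b")))
    stop("channel names must end in 'a' or 'b'")
  list(names = pairs, a = ia, b = ib)
}

#' Combine planar gradiometer pairs by root-mean-square
#'
#' Per pair and sample, `out = sqrt((a^2 + b^2) / 2)` (convention `"mean"`,
#' the literal root-mean-square of the two gradients) or
#' `sqrt(a^2 + b^2)` (convention `"sum"`, the common vector-magnitude
#' alternative; the two differ by a global factor sqrt(2), to which all
#' inferential results are invariant). The result is non-negative and the
#' channel count halves.
#'
#' @param x An uncombined [EpochSet-class] or [Evoked-class].
#' @param convention `"mean"` (default) or `"sum"`.
#' @return The combined object of the same type.
#' @export
setGeneric("combinePlanar", function(x, convention = c("mean", "sum"))
  standardGeneric("combinePlanar"))

#' @rdname combinePlanar
#' @export
setMethod("combinePlanar", "EpochSet", function(x, convention) {
  convention <- match.arg(convention)
  if (x@combined) stop("already combined")
  pi_ <- .pairIndex(x@channelNames)
  denom <- if (convention == "mean") 2 else 1
  comb <- sqrt((x@data[, pi_$a, , drop = FALSE]^2 +
                  x@data[, pi_$b, , drop = FALSE]^2) / denom)
  initialize(x, data = comb, channelNames = pi_$names, combined = TRUE)
})

#' @rdname combinePlanar
#' @export
setMethod("combinePlanar", "Evoked", function(x, convention) {
  convention <- match.arg(convention)
  if (x@combined) stop("already combined")
  pi_ <- .pairIndex(x@channelNames)
  denom <- if (convention == "mean") 2 else 1
  comb <- sqrt((x@data[pi_$a, , drop = FALSE]^2 +
                  x@data[pi_$b, , drop = FALSE]^2) / denom)
  rownames(comb) <- pi_$names
  initialize(x, data = comb, channelNames = pi_$names, combined = TRUE)
})

#' Baseline-correct epochs or evokeds
#'
#' Subtracts, per channel (and trial), the mean over the baseline window
#' (default the 50 ms pre-stimulus interval). Idempotent.
#'
#' @param x An [EpochSet-class], [Evoked-class] or [MMNmWave-class].
#' @param windowS Baseline window in seconds (default `c(-0.050, 0)`).
#' @return The baseline-corrected object.
#' @export
setGeneric("baselineCorrect", function(x, windowS = c(-0.050, 0))
  standardGeneric("baselineCorrect"))

#' @rdname baselineCorrect
#' @export
setMethod("baselineCorrect", "EpochSet", function(x, windowS) {
  idx <- windowIndices(timePoints(x), windowS)
  bl <- apply(x@data[, , idx, drop = FALSE], c(1, 2), mean)
  x@data <- x@data - array(bl, dim(x@data))
  x
})

.baselineMatrix <- function(M, times, windowS) {
  idx <- windowIndices(times, windowS)
  M - rowMeans(M[, idx, drop = FALSE])
}

#' @rdname baselineCorrect
#' @export
setMethod("baselineCorrect", "Evoked", function(x, windowS) {
  x@data <- .baselineMatrix(x@data, timePoints(x), windowS)
  x
})

#' @rdname baselineCorrect
#' @export
setMethod("baselineCorrect", "MMNmWave", function(x, windowS) {
  x@data <- .baselineMatrix(x@data, timePoints(x), windowS)
  x
})

#' Average trials of one condition
#'
#' Arithmetic mean over the trials of a condition. Standard trials are
#' restricted to analysis standards (the third standard after each deviant).
#'
#' @param epochs An [EpochSet-class].
#' @param condition Condition code.
#' @return An [Evoked-class].
#' @export
averageCondition <- function(epochs, condition) {
  condition <- match.arg(condition, .allConditions())
  sel <- epochs@condition == condition
  if (condition == "STD") sel <- sel & epochs@analysisStandard
  if (!any(sel)) stop("no trials of condition ", condition)
  sub <- epochs@data[sel, , , drop = FALSE]
  avg <- apply(sub, c(2, 3), mean)
  rownames(avg) <- epochs@channelNames
  methods::new("Evoked", data = avg, condition = condition,
               nTrials = sum(sel), channelNames = epochs@channelNames,
               fsHz = epochs@fsHz, t0S = epochs@t0S,
               subjectId = epochs@subjectId, group = epochs@group,
               paradigm = epochs@paradigm, combined = epochs@combined)
}

#' Full preprocessing chain
#'
#' Applies, in fixed order: jump rejection, band-pass filtering, planar RMS
#' combination, baseline correction, and per-condition averaging. The order
#' mirrors standard evoked-field practice; note that baseline correction
#' after RMS combination subtracts the baseline of the rectified signal.
#'
#' @param epochs A raw (uncombined) [EpochSet-class].
#' @param zCutoff Jump rejection threshold.
#' @param lowHz,highHz,order,padS Band-pass parameters (see [bandpass()]).
#' @param baselineWindowS Baseline window.
#' @param convention RMS convention (see [combinePlanar()]).
#' @param conditions Conditions to average (default: all present).
#' @param verbose Log stage effects with `message()`.
#' @return List with `evoked` (named list of combined [Evoked-class]) and
#'   `report` (the [RejectionReport-class]).
#' @export
preprocessPipeline <- function(epochs, zCutoff = 30, lowHz = 1, highHz = 40,
                               order = 4, padS = 3,
                               baselineWindowS = c(-0.050, 0),
                               convention = "mean", conditions = NULL,
                               verbose = FALSE) {
  stopifnot(is(epochs, "EpochSet"), !epochs@combined)
  rj <- rejectJumps(epochs, zCutoff)
  if (verbose)
    message(sprintf("rejection: %d/%d trials retained (%.1f%%)",
                    rj$report@nTotal - rj$report@nRejected, rj$report@nTotal,
                    100 * rj$report@retainedFraction))
  x <- bandpass(rj$epochs, lowHz = lowHz, highHz = highHz, order = order,
                padS = padS)
  x <- combinePlanar(x, convention)
  x <- baselineCorrect(x, baselineWindowS)
  if (is.null(conditions)) {
    conditions <- intersect(.allConditions(), unique(x@condition))
    if (!any(x@analysisStandard)) conditions <- setdiff(conditions, "STD")
  }
  evoked <- lapply(conditions, function(cn) averageCondition(x, cn))
  names(evoked) <- conditions
  if (verbose)
    message("averaged conditions: ", paste(conditions, collapse = ", "))
  list(evoked = evoked, report = rj$report)
}
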