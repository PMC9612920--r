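## Shared helpers: deviant-type algebra, seeded evaluation, time axes.

#' Deviant type codes
#'
#' The seven deviant types of the multi-feature oddball design: single-feature
#' deviants in frequency (`F`), intensity (`I`) and perceived location (`L`),
#' the three pairwise combinations (`FI`, `IL`, `LF`) and the triple (`FIL`).
#' `"STD"` denotes the standard (non-deviant) condition.
#'
#' @return Character vector of the seven deviant codes (standard excluded).
#' @examples
#' deviantTypes()
#' @export
deviantTypes <- function() c("F", "I", "L", "FI", "IL", "LF", "FIL")

.allConditions <- function() c("STD", deviantTypes())

#' Constituent features of a deviant type
#'
#' @param code A condition code (`"STD"` or one of [deviantTypes()]).
#' @return Character vector of constituent single features (empty for `"STD"`).
#' @examples
#' deviantConstituents("LF")
#' @export
deviantConstituents <- function(code) {
  code <- match.arg(code, .allConditions())
  switch(code,
    STD = character(0),
    F = "F", I = "I", L = "L",
    FI = c("F", "I"), IL = c("I", "L"), LF = c("L", "F"),
    FIL = c("F", "I", "L"))
}

## canonical code for a set of single features
.constituentsToCode <- function(feats) {
  feats <- sort(unique(feats))
  key <- paste(feats, collapse = "")
  code <- c(F = "F", I = "I", L = "L",
            FI = "FI", IL = "IL", FL = "LF", FIL = "FIL")[key]
  if (is.na(code)) stop("not a valid constituent set: ", key)
  unname(code)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Derive k reproducible child seeds (< 2^31) from a master seed.
deriveSeeds <- function(masterSeed, k) {
  withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, k))
}

## Time axis for an epoch window (inclusive endpoints).
timeAxis <- function(fsHz, windowS = c(-0.100, 0.400)) {
  n <- round((windowS[2] - windowS[1]) * fsHz)
  windowS[1] + (0:n) / fsHz
}

## Indices of samples falling inside [windowS[1], windowS[2]].
windowIndices <- function(times, windowS) {
  idx <- which(times >= windowS[1] - 1e-9 & times <= windowS[2] + 1e-9)
  if (length(idx) == 0L) stop("window contains no samples")
  idx
}
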