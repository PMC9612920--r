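## Generative model of planar-gradiometer epochs: sensor layout, evoked
## components, ground-truth subadditivity, correlated noise, jump artifacts.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic MEG cohort. The defaults encode
#' the study conditions: two groups of 25 subjects, 144 trials per deviant
#' type, 250 Hz epochs spanning -100..+400 ms, feature-specific mismatch
#' components peaking at 156 ms over bilateral temporal sensor regions, a
#' standard evoked response peaking at 100 ms over a spatially disjoint
#' central region, and a group- and combination-specific subadditivity
#' coefficient kappa that shrinks the summed single-feature mismatch
#' components of double/triple deviants by (1 - kappa).
#'
#' No evoked amplitudes (fT/cm) are reported for the original recordings, so
#' the amplitude and noise defaults are the package's own choices: component
#' amplitudes 10 (standard 15) in arbitrary field-gradient units and
#' single-trial noise SD chosen so single-trial SNR at the mismatch peak is
#' about 0.3.
#'
#' The three feature components share one latency and width by default;
#' their topography centers are displaced a few millimeters apart around the
#' temporal hotspots, mimicking spatially separate neural sources. Standard
#' and mismatch topographies have compactly supported, non-overlapping
#' sensor footprints, which makes the additive model exact under kappa = 0
#' even through the rectifying planar RMS combination (see the methods
#' vignette).
#'
#' @param nSubjectsPerGroup Subjects per group.
#' @param groups Group labels (expert, control).
#' @param trialsPerDeviant Trials per deviant type (and analysis standards).
#' @param fsHz Sampling rate, Hz.
#' @param windowS Epoch window (seconds relative to stimulus onset).
#' @param features Per-feature component parameters: `beta` (amplitude),
#'   `latency` (s), `width` (Gaussian SD, s), `offset` (3-vector tangential
#'   displacement of the topography center, meters).
#' @param standard Standard-response parameters: `amplitude`, `latency`,
#'   `width`, `spread`, `trunc` (topography Gaussian SD and support radius).
#' @param mismatch Shared mismatch topography parameters `spread`, `trunc`.
#' @param kappa Named list per group; each a named vector over
#'   `FI`, `IL`, `LF`, `FIL` with values in `[0, 1]`. Singles and standards
#'   always have kappa = 0. The default gives musicians kappa = 0.4 for the
#'   frequency-containing combinations only, non-musicians zero everywhere.
#' @param noise `lambda` (spatial correlation length, m), `phi` (temporal
#'   AR(1) coefficient), `sigma` (single-trial noise SD), `subjectCV`
#'   (inter-subject log-normal amplitude CV).
#' @param artifact `pJump` (probability a trial receives a SQUID-like jump),
#'   `amplitude` (step size; default 50 * noise sigma).
#' @param seed Default seed recorded with the configuration.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
    nSubjectsPerGroup = 25,
    groups = c("musician", "nonmusician"),
    trialsPerDeviant = 144,
    fsHz = 250,
    windowS = c(-0.100, 0.400),
    features = list(
      F = list(beta = 10, latency = 0.156, width = 0.030,
               offset = c(0, 0.010, 0)),
      I = list(beta = 10, latency = 0.156, width = 0.030,
               offset = c(0, -0.010, 0)),
      L = list(beta = 10, latency = 0.156, width = 0.030,
               offset = c(0, 0, 0.010))),
    standard = list(amplitude = 15, latency = 0.100, width = 0.025,
                    spread = 0.020, trunc = 0.042),
    mismatch = list(spread = 0.018, trunc = 0.045),
    kappa = list(
      musician = c(FI = 0.4, IL = 0, LF = 0.4, FIL = 0.4),
      nonmusician = c(FI = 0, IL = 0, LF = 0, FIL = 0)),
    noise = list(lambda = 0.06, phi = 0.7, sigma = 33.3, subjectCV = 0.2),
    artifact = list(pJump = 0, amplitude = NULL),
    seed = 1L) {
  stopifnot(length(groups) == 2, all(c("F", "I", "L") %in% names(features)))
  names(kappa) <- groups[seq_along(kappa)]
  for (g in names(kappa)) {
    k <- kappa[[g]]
    if (any(k < 0 | k > 1)) stop("kappa values must lie in [0, 1]")
    if (!all(c("FI", "IL", "LF", "FIL") %in% names(k)))
      stop("kappa must name FI, IL, LF and FIL")
  }
  nSamp <- (windowS[2] - windowS[1]) * fsHz
  if (abs(nSamp - round(nSamp)) > 1e-9)
    stop("fsHz * window span must give an integer sample count")
  if (is.null(artifact$amplitude)) artifact$amplitude <- 50 * noise$sigma
  if (noise$sigma < 0) stop("noise sigma must be non-negative")
  structure(list(
    nSubjectsPerGroup = nSubjectsPerGroup, groups = groups,
    trialsPerDeviant = trialsPerDeviant, fsHz = fsHz, windowS = windowS,
    features = features, standard = standard, mismatch = mismatch,
    kappa = kappa, noise = noise, artifact = artifact,
    seed = as.integer(seed)), class = "SimulationConfig")
}

#' Synthetic planar-gradiometer layout
#'
#' Places `nPairs` gradiometer pairs quasi-uniformly (Fibonacci lattice with
#' a small seeded jitter) on an upper hemisphere of the given radius, labels
#' hemispheres by the lateral coordinate, assigns each site a fixed
#' combination phase psi, and designates left/right temporal hotspot centers
#' where mismatch topographies peak.
#'
#' @param nPairs Number of pairs (>= 10; default 51, half the 102-site
#'   whole-head gradiometer array the simulation stands in for).
#' @param seed Integer seed.
#' @param radius Helmet radius, meters.
#' @return A [SensorLayout-class].
#' @examples
#' makeLayout(51, seed = 1)
#' @export
makeLayout <- function(nPairs = 51, seed = 1, radius = 0.09) {
  if (nPairs < 10)
    stop("nPairs must be >= 10; neighborhood structure degenerates")
  withSeed(seed, {
    i <- seq_len(nPairs)
    z <- (i - 0.5) / nPairs * radius              # area-uniform on hemisphere
    az <- 2 * pi * i * (1 + sqrt(5)) / 2
    rho <- sqrt(radius^2 - z^2)
    pos <- cbind(x = rho * cos(az), y = rho * sin(az), z = z)
    pos <- pos + matrix(stats::rnorm(3 * nPairs, sd = 5e-4), ncol = 3)
    pos <- pos * radius / sqrt(rowSums(pos^2))    # back onto the sphere
    hemi <- ifelse(pos[, "x"] < -0.005, "left",
                   ifelse(pos[, "x"] > 0.005, "right", "midline"))
    name <- sprintf("P%03d", i)
    pairs <- data.frame(
      pair_id = i, name = name,
      name_a = paste0(name, "a"), name_b = paste0(name, "b"),
      x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
      hemisphere = hemi, psi = stats::runif(nPairs, 0, 2 * pi))
    el <- 20 * pi / 180
    hotspots <- list(
      left = c(-radius * cos(el), 0, radius * sin(el)),
      right = c(radius * cos(el), 0, radius * sin(el)))
    methods::new("SensorLayout", pairs = pairs, radius = radius,
                 hotspots = hotspots, seed = as.integer(seed))
  })
}

## Raw channel names of a layout, interleaved (P001a, P001b, P002a, ...).
.rawChannelNames <- function(layout) {
  as.vector(rbind(layout@pairs$name_a, layout@pairs$name_b))
}

## Compactly supported topography: Gaussian falloff under a cosine taper
## that reaches exactly zero at distance `trunc` from `center`.
.pairTopography <- function(layout, center, spread, trunc) {
  p <- layout@pairs
  d <- sqrt((p$x - center[1])^2 + (p$y - center[2])^2 + (p$z - center[3])^2)
  ifelse(d < trunc,
         exp(-d^2 / (2 * spread^2)) * 0.5 * (1 + cos(pi * d / trunc)),
         0)
}

## Bilateral mismatch topography for one feature (left + right hotspot lobes).
.featureTopography <- function(layout, config, feature) {
  f <- config$features[[feature]]
  sp <- config$mismatch$spread; tr <- config$mismatch$trunc
  .pairTopography(layout, layout@hotspots$left + f$offset, sp, tr) +
    .pairTopography(layout, layout@hotspots$right + f$offset, sp, tr)
}

#' Gaussian-windowed evoked component waveform
#'
#' Monophasic component `w(t) = amplitude * exp(-(t - latency)^2 /
#' (2 width^2))` sampled on the epoch time axis.
#'
#' @param latencyS Peak latency (s); must fall inside the window.
#' @param widthS Gaussian SD (s), > 0.
#' @param amplitude Peak amplitude.
#' @param fsHz Sampling rate.
#' @param windowS Epoch window.
#' @return Numeric vector, one value per sample.
#' @export
componentWaveform <- function(latencyS, widthS, amplitude, fsHz = 250,
                              windowS = c(-0.100, 0.400)) {
  if (widthS <= 0) stop("widthS must be positive")
  if (latencyS < windowS[1] || latencyS > windowS[2])
    stop("latency must lie within the epoch window")
  t <- timeAxis(fsHz, windowS)
  amplitude * exp(-(t - latencyS)^2 / (2 * widthS^2))
}

## Pair-level signal magnitude (pairs x time) for one condition.
.pairSignal <- function(dev, group, config, layout) {
  std <- config$standard
  tot <- outer(.pairTopography(layout, c(0, 0, layout@radius),
                               std$spread, std$trunc),
               componentWaveform(std$latency, std$width, std$amplitude,
                                 config$fsHz, config$windowS))
  feats <- deviantConstituents(dev)
  if (length(feats) > 0) {
    k <- if (length(feats) >= 2) config$kappa[[group]][[dev]] else 0
    for (f in feats) {
      fc <- config$features[[f]]
      tot <- tot + (1 - k) *
        outer(.featureTopography(layout, config, f),
              componentWaveform(fc$latency, fc$width, fc$beta,
                                config$fsHz, config$windowS))
    }
  }
  tot
}

#' Noise-free evoked field of a condition
#'
#' The deterministic raw-channel response `E = S + (1 - kappa) * sum of the
#' constituent mismatch components`, where `S` is the standard evoked field,
#' each component is a separable topography x Gaussian waveform, and kappa
#' is the group/combination subadditivity coefficient (0 for standards and
#' single deviants). The pair-level magnitude `b` is projected onto the two
#' orthogonal gradiometers of each site as `b cos(psi)` and `b sin(psi)`
#' with the site's fixed phase, so RMS combination recovers `|b|` up to the
#' combination convention.
#'
#' @param dev Condition code (`"STD"` or a deviant type).
#' @param group Group label (must match a name of `config$kappa`).
#' @param config A [simulationConfig()].
#' @param layout A [SensorLayout-class].
#' @return Matrix, raw channels (2 * nPairs) x time.
#' @export
trueEvoked <- function(dev, group, config, layout) {
  if (!group %in% names(config$kappa)) stop("unknown group: ", group)
  dev <- match.arg(dev, .allConditions())
  tot <- .pairSignal(dev, group, config, layout)
  psi <- layout@pairs$psi
  out <- matrix(0, 2 * nPairs(layout), ncol(tot))
  out[seq(1, nrow(out), 2), ] <- tot * cos(psi)
  out[seq(2, nrow(out), 2), ] <- tot * sin(psi)
  rownames(out) <- .rawChannelNames(layout)
  out
}

## Spatially (exp(-d/lambda) across sites; orthogonal channels of one site
## independent) and temporally (AR(1)) correlated unit-variance noise.
## Returns array (2*nPairs, nTrials, nT).
.noiseArray <- function(layout, nTrials, nT, lambda, phi) {
  nP <- nPairs(layout)
  p <- layout@pairs
  D <- as.matrix(stats::dist(cbind(p$x, p$y, p$z)))
  R <- chol(exp(-D / lambda) + diag(1e-9, nP))
  draw <- function() crossprod(R, matrix(stats::rnorm(nP * nTrials * nT),
                                         nP, nTrials * nT))
  E <- matrix(0, 2 * nP, nTrials * nT)
  E[seq(1, 2 * nP, 2), ] <- draw()
  E[seq(2, 2 * nP, 2), ] <- draw()
  dim(E) <- c(2 * nP, nTrials, nT)
  if (phi != 0) {
    s <- sqrt(1 - phi^2)
    for (t in 2:nT) E[, , t] <- phi * E[, , t - 1] + s * E[, , t]
  }
  E
}

#' Simulate raw-pair epochs for one subject
#'
#' Every trial is the condition's noise-free evoked field scaled by a
#' subject-specific log-normal gain, plus stationary Gaussian noise with
#' spatial covariance `exp(-d / lambda)` across sites and AR(1) temporal
#' structure.
#'
#' @inheritParams trueEvoked
#' @param subjectId Subject identifier.
#' @param seed Per-subject seed.
#' @param trialsPerDeviant Trials per condition (default from `config`;
#'   must be >= 8). Standard trials (already restricted to analysis
#'   standards) are simulated in equal number.
#' @param conditions Conditions to simulate (default all eight).
#' @return An uncombined [EpochSet-class].
#' @export
simulateSubject <- function(config, layout, group, subjectId, seed,
                            trialsPerDeviant = config$trialsPerDeviant,
                            conditions = .allConditions(),
                            paradigm = "none") {
  if (trialsPerDeviant < 8) stop("trialsPerDeviant must be >= 8")
  if (config$noise$sigma < 0) stop("noise sigma must be non-negative")
  nT <- length(timeAxis(config$fsHz, config$windowS))
  nC <- 2 * nPairs(layout)
  withSeed(seed, {
    cv <- config$noise$subjectCV
    gain <- if (cv > 0) {
      sdl <- sqrt(log(1 + cv^2))
      stats::rlnorm(1, -sdl^2 / 2, sdl)
    } else 1
    nTotal <- trialsPerDeviant * length(conditions)
    dat <- array(0, c(nTotal, nC, nT))
    cond <- character(nTotal)
    row <- 0L
    for (cn in conditions) {
      sig <- gain * trueEvoked(cn, group, config, layout)
      idx <- row + seq_len(trialsPerDeviant)
      if (config$noise$sigma > 0) {
        noi <- config$noise$sigma *
          .noiseArray(layout, trialsPerDeviant, nT,
                      config$noise$lambda, config$noise$phi)
        for (tr in seq_len(trialsPerDeviant))
          dat[idx[tr], , ] <- sig + noi[, tr, ]
      } else {
        for (tr in idx) dat[tr, , ] <- sig
      }
      cond[idx] <- cn
      row <- row + trialsPerDeviant
    }
    methods::new("EpochSet", data = dat,
                 channelNames = .rawChannelNames(layout),
                 fsHz = config$fsHz, t0S = config$windowS[1],
                 condition = cond, analysisStandard = cond == "STD",
                 subjectId = subjectId, group = group, paradigm = paradigm,
                 combined = FALSE,
                 misc = list(seed = as.integer(seed), gain = gain))
  })
}

#' Simulate subject-level averaged evokeds directly
#'
#' Study-scale shortcut used by the validation experiments: instead of
#' simulating and averaging single trials, draws each condition's trial
#' average directly (signal x subject gain + noise scaled by 1/sqrt(n)).
#' Averaging is linear, so the average of `n` simulated trials and this
#' direct draw have the same distribution. With `halves = TRUE` two
#' independent half-averages (each of n/2 trials) are returned per
#' condition, as needed by the split-half subadditivity estimator.
#'
#' @inheritParams simulateSubject
#' @param halves Return two independent half-averages per condition.
#' @return Named list (by condition) of uncombined [Evoked-class] objects,
#'   or, with `halves = TRUE`, of two-element lists of them.
#' @export
simulateSubjectEvoked <- function(config, layout, group, subjectId, seed,
                                  trialsPerDeviant = config$trialsPerDeviant,
                                  conditions = .allConditions(),
                                  halves = FALSE, paradigm = "none") {
  nT <- length(timeAxis(config$fsHz, config$windowS))
  withSeed(seed, {
    cv <- config$noise$subjectCV
    gain <- if (cv > 0) {
      sdl <- sqrt(log(1 + cv^2))
      stats::rlnorm(1, -sdl^2 / 2, sdl)
    } else 1
    nDraw <- if (halves) 2L else 1L
    nEff <- trialsPerDeviant / nDraw
    sdEvoked <- config$noise$sigma / sqrt(nEff)
    out <- list()
    for (cn in conditions) {
      sig <- gain * trueEvoked(cn, group, config, layout)
      mk <- function() {
        noi <- if (sdEvoked > 0)
          sdEvoked * .noiseArray(layout, 1L, nT, config$noise$lambda,
                                 config$noise$phi)[, 1, ]
        else 0
        methods::new("Evoked", data = sig + noi,
                     condition = cn, nTrials = nEff,
                     channelNames = .rawChannelNames(layout),
                     fsHz = config$fsHz, t0S = config$windowS[1],
                     subjectId = subjectId, group = group,
                     paradigm = paradigm, combined = FALSE)
      }
      out[[cn]] <- if (halves) list(mk(), mk()) else mk()
    }
    out
  })
}

#' Inject SQUID-like jump artifacts
#'
#' Adds, to a random fraction `pJump` of trials, a step of the given
#' amplitude (random sign) on one random channel starting at a random
#' sample. Affected trials are recorded in `misc$jumpTrials` so rejection
#' can be validated against ground truth.
#'
#' @param epochs An uncombined [EpochSet-class].
#' @param pJump Per-trial jump probability in `[0, 1]`.
#' @param amplitude Step amplitude.
#' @param seed Integer seed.
#' @return The modified [EpochSet-class].
#' @export
injectJumps <- function(epochs, pJump, amplitude, seed) {
  stopifnot(is(epochs, "EpochSet"), pJump >= 0, pJump <= 1)
  d <- dim(epochs@data)
  withSeed(seed, {
    hit <- which(stats::runif(d[1]) < pJump)
    info <- data.frame(trial = hit,
                       channel = sample.int(d[2], length(hit), replace = TRUE),
                       sample = sample(2:d[3], length(hit), replace = TRUE),
                       sign = sample(c(-1, 1), length(hit), replace = TRUE))
    for (k in seq_along(hit)) {
      tr <- info$trial[k]
      epochs@data[tr, info$channel[k], info$sample[k]:d[3]] <-
        epochs@data[tr, info$channel[k], info$sample[k]:d[3]] +
        info$sign[k] * amplitude
    }
    epochs@misc$jumpTrials <- hit
    epochs@misc$jumpInfo <- info
    epochs
  })
}
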