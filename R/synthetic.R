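#' @include qc.R
NULL

#' Construct a scenario specification
#'
#' See \code{\linkS4class{ScenarioSpec}} for the meaning of every component.
#' Defaults give a quiet two-channel recording with no noise; the named
#' study scenarios live in \code{\link{standardScenarios}}.
#'
#' @param nChannels,fs,durationS,seed geometry and reproducibility.
#' @param trend polynomial drift coefficients (per second^k).
#' @param oscillators data.frame(freq, amplitude, phase).
#' @param noiseSd white measurement noise SD.
#' @param spikes,steps artifact tables (data.frame(time_s, amplitude/size,
#'   channel); channel NA = all channels).
#' @param superficialWeight per-channel weight of the shared scalp
#'   component.
#' @param shortChannels ids of short-separation channels.
#' @param hbrRatio neural HbR/HbO scaling (default -1/3).
#' @param taskDesign optional \code{TaskDesign}.
#' @param betas per-condition true effect amplitudes.
#' @param covariance optional true neural inter-channel covariance.
#' @return a \code{ScenarioSpec}.
#' @export
scenarioSpec <- function(nChannels = 2, fs = 10, durationS = 60, seed = 1,
                         trend = c(0, 0),
                         oscillators = data.frame(freq = numeric(0),
                                                  amplitude = numeric(0),
                                                  phase = numeric(0)),
                         noiseSd = 0, spikes = NULL, steps = NULL,
                         superficialWeight = 0,
                         shortChannels = integer(0), hbrRatio = -1/3,
                         taskDesign = NULL, betas = numeric(0),
                         covariance = NULL) {
  emptyArt <- data.frame(time_s = numeric(0), amplitude = numeric(0),
                         channel = integer(0))
  if (is.null(spikes)) spikes <- emptyArt
  if (is.null(steps))
    steps <- data.frame(time_s = numeric(0), size = numeric(0),
                        channel = integer(0))
  new("ScenarioSpec", nChannels = as.integer(nChannels), fs = fs,
      durationS = durationS, seed = as.integer(seed), trend = trend,
      oscillators = oscillators, noiseSd = noiseSd, spikes = spikes,
      steps = steps, superficialWeight = superficialWeight,
      shortChannels = as.integer(shortChannels), hbrRatio = hbrRatio,
      taskDesign = taskDesign, betas = betas, covariance = covariance)
}

# smooth unit-sd random series, one per column: low-pass filtered white noise
.smoothNoise <- function(T, C, fs, cutoff = 0.1) {
  E <- matrix(stats::rnorm(T * C), T, C)
  if (fs / 2 > cutoff * 1.5) {
    bt <- signal::butter(2, cutoff / (fs / 2), type = "low")
    E <- .filtfiltPadMat(bt$b, bt$a, E)
  }
  sweep(E, 2, apply(E, 2, stats::sd), "/")
}

#' Generate a synthetic recording with known ground truth
#'
#' Builds an HbO/HbR recording from the scenario's components:
#' \code{HbO = trend + oscillators + neural + superficial + task + artifacts
#' + noise}, where the neural part (random smooth series with the requested
#' inter-channel covariance, plus HRF-convolved task responses) enters HbR
#' scaled by \code{hbrRatio} (negative: physiologically anticorrelated)
#' while artifacts and the superficial component enter both chromophores
#' with the same sign (common-mode), which is exactly the premise CBSI-style
#' motion correction relies on. Identical spec and seed give
#' bitwise-identical output.
#'
#' @param spec a \code{ScenarioSpec}.
#' @return list with elements \code{recording} (a \code{NirsRecording}) and
#'   \code{truth} (every injected component as a T x C matrix, plus the
#'   artifact-free \code{hboClean}/\code{hbrClean} references and the spec).
#' @export
generateScenario <- function(spec) {
  stopifnot(is(spec, "ScenarioSpec"))
  validObject(spec)
  set.seed(spec@seed)
  fs <- spec@fs
  T <- round(spec@durationS * fs)
  C <- spec@nChannels
  t <- (seq_len(T) - 1) / fs

  trend <- numeric(T)
  for (k in seq_along(spec@trend))
    trend <- trend + spec@trend[k] * t^(k - 1)
  osc <- numeric(T)
  if (nrow(spec@oscillators))
    for (r in seq_len(nrow(spec@oscillators)))
      osc <- osc + spec@oscillators$amplitude[r] *
        cos(2 * pi * spec@oscillators$freq[r] * t + spec@oscillators$phase[r])
  shared <- trend + osc

  neural <- matrix(0, T, C)
  if (!is.null(spec@covariance)) {
    Z <- .smoothNoise(T, C, fs)
    neural <- Z %*% chol(spec@covariance)
  }
  task <- matrix(0, T, C)
  if (!is.null(spec@taskDesign)) {
    dm <- buildDesign(spec@taskDesign, T, fs)
    conds <- setdiff(dm@labels, "constant")
    B <- rep_len(spec@betas, length(conds))
    task <- matrix(rep(dm@X[, seq_along(conds), drop = FALSE] %*% B, C), T, C)
  }
  superficial <- .smoothNoise(T, 1, fs, cutoff = 0.15)[, 1] +
    0.5 * cos(2 * pi * 0.1 * t + 1)
  supW <- rep_len(spec@superficialWeight, C)
  supMat <- outer(superficial, supW)
  isShort <- seq_len(C) %in% spec@shortChannels

  artifacts <- matrix(0, T, C)
  addArt <- function(art, tbl, stepLike) {
    for (r in seq_len(nrow(tbl))) {
      i <- min(max(round(tbl$time_s[r] * fs) + 1, 1), T)
      chs <- if (is.na(tbl$channel[r])) seq_len(C) else tbl$channel[r]
      a <- if (stepLike) tbl$size[r] else tbl$amplitude[r]
      if (stepLike) art[i:T, chs] <- art[i:T, chs] + a
      else art[i, chs] <- art[i, chs] + a
    }
    art
  }
  artifacts <- addArt(artifacts, spec@spikes, FALSE)
  artifacts <- addArt(artifacts, spec@steps, TRUE)

  noiseHbO <- matrix(stats::rnorm(T * C, sd = spec@noiseSd), T, C)
  noiseHbR <- matrix(stats::rnorm(T * C, sd = spec@noiseSd), T, C)

  neuralTotal <- neural + task
  # short channels see superficial physiology, not the neural signal
  neuralTotal[, isShort] <- 0
  hboClean <- shared + neuralTotal + supMat + noiseHbO
  hbrClean <- spec@hbrRatio * (osc + neuralTotal) + supMat * abs(spec@hbrRatio) +
    noiseHbR
  hbo <- hboClean + artifacts
  hbr <- hbrClean + artifacts

  channels <- defaultChannelTable(C)
  channels$is_short <- isShort
  rec <- NirsRecording(cbind(hbo, hbr), fs = fs, kind = "hb",
                       chromophores = c("HbO", "HbR"), channels = channels)
  rec <- appendHistory(rec, "simulate", list(seed = spec@seed))
  list(recording = rec,
       truth = list(time = t, trend = trend, oscillators = osc,
                    neural = neuralTotal, task = task,
                    superficial = supMat, artifacts = artifacts,
                    noiseHbO = noiseHbO, noiseHbR = noiseHbR,
                    hboClean = hboClean, hbrClean = hbrClean,
                    betas = spec@betas, taskDesign = spec@taskDesign,
                    covariance = spec@covariance, spec = spec))
}

#' Named study scenarios
#'
#' Ships the package's reference simulation conditions:
#' \describe{
#'   \item{rest44}{one resting-state subject: 44 channels (two standard 3x5
#'     probes, 22 channels each), 7 min at 10 Hz; slow neural oscillation,
#'     Mayer wave (0.1 Hz), respiration (0.3 Hz), cardiac (1 Hz),
#'     block-structured inter-channel covariance.}
#'   \item{task_finger}{a 9-subject finger-tapping block experiment on the
#'     same 44-channel montage: 20 s tapping blocks alternating with 20 s
#'     rest, true activation amplitude 0.8; one spec per subject (seeds
#'     differ, design shared).}
#'   \item{motion_heavy}{4 channels, 2 min, clean slow oscillation plus
#'     large spike and baseline-step artifacts for motion-correction
#'     validation.}
#'   \item{short_channel}{10 channels of which 2 are short-separation
#'     references carrying only superficial physiology.}
#' }
#'
#' @param nSubjectsRest number of resting subjects when expanded with
#'   \code{\link{expandSubjects}} (informational; rest44 itself is one
#'   subject).
#' @return named list; \code{task_finger} is a list of 9 specs, the others
#'   single \code{ScenarioSpec} objects.
#' @export
standardScenarios <- function(nSubjectsRest = 9) {
  osc <- data.frame(freq = c(0.03, 0.1, 0.3, 1.0),
                    amplitude = c(0.5, 0.2, 0.15, 0.1),
                    phase = c(0, 1, 2, 3))
  blockCov <- function(C, blocks = 2, within = 0.3, between = 0.1, v = 0.25) {
    b <- rep(seq_len(blocks), each = ceiling(C / blocks))[seq_len(C)]
    S <- matrix(between, C, C)
    for (k in seq_len(blocks)) S[b == k, b == k] <- within
    diag(S) <- 1
    S * v
  }
  rest44 <- scenarioSpec(nChannels = 44, fs = 10, durationS = 420,
                         seed = 4401, trend = c(0, 0.002),
                         oscillators = osc, noiseSd = 0.1,
                         covariance = blockCov(44))
  tapping <- TaskDesign(data.frame(condition = "tapping",
                                   onset_s = 10 + 40 * (0:7),
                                   duration_s = 20))
  taskFinger <- lapply(1:9, function(s)
    scenarioSpec(nChannels = 44, fs = 10, durationS = 340, seed = 9000 + s,
                 oscillators = osc[2:4, ], noiseSd = 0.15,
                 taskDesign = tapping, betas = 0.8,
                 covariance = blockCov(44, v = 0.04)))
  motionHeavy <- scenarioSpec(
    nChannels = 4, fs = 10, durationS = 120, seed = 777,
    oscillators = data.frame(freq = 0.05, amplitude = 1, phase = 0),
    noiseSd = 0.05,
    spikes = data.frame(time_s = c(30, 83.7), amplitude = c(5, -4),
                        channel = c(NA, NA)),
    steps = data.frame(time_s = 55, size = 7, channel = NA))
  shortChannel <- scenarioSpec(
    nChannels = 10, fs = 10, durationS = 180, seed = 55,
    oscillators = osc[1, , drop = FALSE], noiseSd = 0.05,
    superficialWeight = c(rep(0.5, 8), 1, 1), shortChannels = c(9L, 10L),
    covariance = diag(0.25, 10))
  list(rest44 = rest44, task_finger = taskFinger,
       motion_heavy = motionHeavy, short_channel = shortChannel)
}

#' Derive per-subject specs from one scenario
#'
#' Clones a spec with consecutive seeds, modelling a group of subjects
#' measured under identical conditions.
#'
#' @param spec a \code{ScenarioSpec}.
#' @param n number of subjects.
#' @return list of \code{ScenarioSpec} objects with seeds
#'   \code{seed + 0:(n-1)}.
#' @export
expandSubjects <- function(spec, n) {
  lapply(seq_len(n) - 1L, function(k) initialize(spec, seed = spec@seed + k))
}

#' Write scenario recordings to disk
#'
#' Emits one file per subject spec, in SNIRF or the manual-CSV dialect.
#'
#' @param specs a \code{ScenarioSpec} or list of them.
#' @param dir output directory (created if needed).
#' @param format "snirf" or "csv".
#' @param prefix file-name prefix.
#' @return character vector of file paths.
#' @export
writeScenarioFiles <- function(specs, dir, format = c("snirf", "csv"),
                               prefix = "subject") {
  format <- match.arg(format)
  if (is(specs, "ScenarioSpec")) specs <- list(specs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(specs))
  for (i in seq_along(specs)) {
    rec <- generateScenario(specs[[i]])$recording
    ext <- if (format == "snirf") "snirf" else "csv"
    paths[i] <- file.path(dir, sprintf("%s%02d.%s", prefix, i, ext))
    if (format == "snirf") writeSnirf(rec, paths[i])
    else writeManualCsv(rec, paths[i])
  }
  paths
}
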