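#' @import methods
NULL

.SIGNAL_KINDS <- c("intensity", "optical_density", "hb")
.CHROMOPHORES <- c("HbO", "HbR", "HbT")

#' NirsRecording: multichannel fNIRS time series
#'
#' The central data container of the package. Holds a time-by-column numeric
#' matrix of either raw optical intensity, optical density, or hemoglobin
#' concentration changes, together with the sampling rate, per-channel
#' metadata and an audit trail of every processing step applied.
#'
#' For \code{signalKind = "hb"} the columns are organised in chromophore
#' blocks: all channels of the first chromophore, then all channels of the
#' second, etc. (e.g. \code{HbO} ch1..chC, then \code{HbR} ch1..chC), so that
#' \code{ncol(data) == nChannels * length(chromophores)}. For
#' \code{"intensity"} and \code{"optical_density"} the blocks are per
#' wavelength in the same layout.
#'
#' @slot data numeric matrix, time points in rows.
#' @slot signalKind one of \code{"intensity"}, \code{"optical_density"},
#'   \code{"hb"}.
#' @slot chromophores ordered subset of \code{c("HbO","HbR","HbT")}; only
#'   meaningful when \code{signalKind == "hb"}.
#' @slot wavelengths numeric wavelengths in nm (intensity / OD kinds).
#' @slot fs sampling rate in Hz.
#' @slot channels data.frame with columns \code{id}, \code{source_idx},
#'   \code{detector_idx}, optional \code{x}, \code{y} (planar layout),
#'   \code{mni_x}, \code{mni_y}, \code{mni_z}, and logical \code{is_short}.
#' @slot history list of processing-step records, each a list with
#'   \code{name}, \code{params}, \code{timestamp}.
#'
#' @export
setClass("NirsRecording",
  representation(
    data = "matrix",
    signalKind = "character",
    chromophores = "character",
    wavelengths = "numeric",
    fs = "numeric",
    channels = "data.frame",
    history = "list"
  ),
  prototype(
    signalKind = "hb",
    chromophores = c("HbO", "HbR"),
    wavelengths = numeric(0),
    history = list()
  )
)

setValidity("NirsRecording", function(object) {
  msg <- character(0)
  if (nrow(object@data) < 2)
    msg <- c(msg, "recording must have at least 2 time points")
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!object@signalKind %in% .SIGNAL_KINDS)
    msg <- c(msg, sprintf("signalKind must be one of %s",
                          paste(.SIGNAL_KINDS, collapse = ", ")))
  nc <- nrow(object@channels)
  if (!all(c("id", "source_idx", "detector_idx") %in% names(object@channels)))
    msg <- c(msg, "channels needs columns id, source_idx, detector_idx")
  else {
    ids <- object@channels$id
    if (!identical(as.integer(ids), seq_len(nc)))
      msg <- c(msg, "channel ids must be unique and contiguous from 1")
    pairs <- paste(object@channels$source_idx, object@channels$detector_idx)
    if (anyDuplicated(pairs))
      msg <- c(msg, "(source_idx, detector_idx) pairs must be unique")
  }
  if (object@signalKind == "hb") {
    if (!length(object@chromophores) ||
        !all(object@chromophores %in% .CHROMOPHORES) ||
        anyDuplicated(object@chromophores))
      msg <- c(msg, "chromophores must be a nonempty unique subset of HbO, HbR, HbT")
    if (ncol(object@data) != nc * length(object@chromophores))
      msg <- c(msg, "ncol(data) must equal nChannels * nChromophores")
    if (all(c("HbO", "HbR", "HbT") %in% object@chromophores)) {
      tot <- .chromBlock(object@data, object@chromophores, nc, "HbO") +
             .chromBlock(object@data, object@chromophores, nc, "HbR")
      dev <- abs(.chromBlock(object@data, object@chromophores, nc, "HbT") - tot)
      if (any(dev > 1e-9, na.rm = TRUE))
        msg <- c(msg, "HbT columns must equal HbO + HbR within 1e-9")
    }
  } else {
    nw <- length(object@wavelengths)
    if (nw == 0 || ncol(object@data) != nc * nw)
      msg <- c(msg, "ncol(data) must equal nChannels * nWavelengths")
  }
  if (length(msg)) msg else TRUE
})

# block extraction helper usable before accessors exist
.chromBlock <- function(data, chroms, nChannels, which) {
  k <- match(which, chroms)
  data[, (k - 1L) * nChannels + seq_len(nChannels), drop = FALSE]
}

#' ProbeSetup: source/detector geometry and channel pairing
#'
#' @slot sources data.frame with columns \code{label}, \code{x}, \code{y}.
#' @slot detectors data.frame with columns \code{label}, \code{x}, \code{y}.
#' @slot pairs integer matrix with columns \code{source}, \code{detector},
#'   one row per measurement channel.
#' @export
setClass("ProbeSetup",
  representation(sources = "data.frame", detectors = "data.frame",
                 pairs = "matrix"))

setValidity("ProbeSetup", function(object) {
  msg <- character(0)
  if (ncol(object@pairs) != 2)
    msg <- c(msg, "pairs must have two columns (source, detector)")
  else {
    if (nrow(object@pairs) &&
        (any(object@pairs[, 1] < 1) || any(object@pairs[, 1] > nrow(object@sources))))
      msg <- c(msg, "pair references a nonexistent source")
    if (nrow(object@pairs) &&
        (any(object@pairs[, 2] < 1) || any(object@pairs[, 2] > nrow(object@detectors))))
      msg <- c(msg, "pair references a nonexistent detector")
  }
  if (length(msg)) msg else TRUE
})

#' TaskDesign: experimental conditions with onsets and durations
#'
#' @slot conditions data.frame with columns \code{condition},
#'   \code{onset_s}, \code{duration_s}; one row per event/epoch.
#' @slot covariates numeric matrix of per-timepoint nuisance columns or a
#'   0-column matrix when absent.
#' @slot perSubject logical; TRUE when the design differs across subjects.
#' @export
setClass("TaskDesign",
  representation(conditions = "data.frame", covariates = "matrix",
                 perSubject = "logical"),
  prototype(covariates = matrix(numeric(0), 0, 0), perSubject = FALSE))

setValidity("TaskDesign", function(object) {
  msg <- character(0)
  cc <- object@conditions
  if (!all(c("condition", "onset_s", "duration_s") %in% names(cc)))
    return("conditions needs columns condition, onset_s, duration_s")
  if (any(cc$onset_s < 0)) msg <- c(msg, "onsets must be nonnegative")
  if (any(cc$duration_s < 0)) msg <- c(msg, "durations must be nonnegative")
  for (cond in unique(cc$condition)) {
    o <- cc$onset_s[cc$condition == cond]
    if (length(o) > 1 && any(diff(o) <= 0))
      msg <- c(msg, sprintf("onsets within condition '%s' must be strictly increasing", cond))
  }
  if (length(msg)) msg else TRUE
})

#' ConnectivityMatrix: channelwise association matrix
#'
#' @slot values numeric symmetric matrix (Pearson r, or Fisher z when
#'   \code{fisherZ} is TRUE).
#' @slot mode one of \code{"roi2roi"}, \code{"roi2whole"}, \code{"wholebrain"}.
#' @slot channelIds integer channel (or ROI) identifiers, one per row.
#' @slot fisherZ logical; values are arctanh(r) when TRUE.
#' @slot thresholdState list: \code{method} ("none", "absolute", "sparsity"),
#'   \code{value}, and for sparsity the \code{attained} edge fraction.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", mode = "character",
                 channelIds = "integer", fisherZ = "logical",
                 thresholdState = "list"),
  prototype(mode = "wholebrain", fisherZ = FALSE,
            thresholdState = list(method = "none")))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) {
    if (object@mode != "roi2whole")
      msg <- c(msg, "values must be square except in roi2whole mode")
  } else if (any(abs(v - t(v)) > 1e-12, na.rm = TRUE)) {
    msg <- c(msg, "values must be symmetric within 1e-12")
  }
  if (length(msg)) msg else TRUE
})

#' ChannelStatMap: per-channel group-level statistic
#'
#' @slot channelIds integer channel identifiers.
#' @slot stat per-channel test statistic (t, F, r or mean).
#' @slot p per-channel two-sided p-values (NA for mean_only).
#' @slot df degrees of freedom (length 1 or 2, or per-channel list collapsed
#'   to the common value).
#' @slot model label of the fitted model.
#' @slot mask logical; channels participating in inference/correction.
#' @slot corrected list with \code{method}, \code{q}, \code{flags} (logical
#'   per channel) once \code{correctMultiple} has been applied.
#' @export
setClass("ChannelStatMap",
  representation(channelIds = "integer", stat = "numeric", p = "numeric",
                 df = "numeric", model = "character", mask = "logical",
                 corrected = "list"),
  prototype(corrected = list(method = "none")))

setValidity("ChannelStatMap", function(object) {
  n <- length(object@channelIds)
  msg <- character(0)
  if (length(object@stat) != n || length(object@p) != n ||
      length(object@mask) != n)
    msg <- c(msg, "stat, p and mask must match channelIds in length")
  if (any(object@p < 0 | object@p > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  fl <- object@corrected$flags
  if (!is.null(fl) && any(fl & !object@mask))
    msg <- c(msg, "significance flags may only be set inside the mask")
  if (length(msg)) msg else TRUE
})

#' SpectrumResult: one-sided amplitude spectrum
#'
#' Represents a real signal as a DC term plus cosine components
#' \eqn{A_k \cos(2\pi f_k t - \phi_k)} at the Fourier frequencies
#' \eqn{f_k = k f_s / N}, \eqn{k = 1..\lfloor N/2 \rfloor}.
#'
#' @slot fk frequencies in Hz.
#' @slot Ak nonnegative amplitudes, same units as the signal.
#' @slot phik phases in radians.
#' @slot a0 DC component (signal mean).
#' @slot N number of time points.
#' @slot fs sampling rate in Hz.
#' @export
setClass("SpectrumResult",
  representation(fk = "numeric", Ak = "numeric", phik = "numeric",
                 a0 = "numeric", N = "integer", fs = "numeric"))

setValidity("SpectrumResult", function(object) {
  msg <- character(0)
  if (length(object@fk) != length(object@Ak) ||
      length(object@fk) != length(object@phik))
    msg <- c(msg, "fk, Ak, phik must have equal length")
  if (any(object@Ak < 0)) msg <- c(msg, "amplitudes must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ALFFResult: per-channel (fractional) amplitude of low-frequency fluctuation
#'
#' @slot table data.frame with columns \code{channel}, \code{alff},
#'   \code{falff}, \code{zalff}, \code{zfalff}.
#' @slot band numeric length-2, analysis band in Hz.
#' @slot Nk number of frequency bins inside the band.
#' @export
setClass("ALFFResult",
  representation(table = "data.frame", band = "numeric", Nk = "integer"))

#' DesignMatrix: GLM design for task activation analysis
#'
#' @slot X numeric T-by-P matrix.
#' @slot labels column labels (conditions, covariates, "constant").
#' @slot fs sampling rate in Hz.
#' @slot hrfParams list of canonical HRF parameters used.
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", labels = "character", fs = "numeric",
                 hrfParams = "list"))

setValidity("DesignMatrix", function(object) {
  msg <- character(0)
  if (ncol(object@X) != length(object@labels))
    msg <- c(msg, "labels must match columns of X")
  if (sum(object@labels == "constant") != 1)
    msg <- c(msg, "design must contain exactly one constant column")
  if (!all(is.finite(object@X))) msg <- c(msg, "design entries must be finite")
  if (length(msg)) msg else TRUE
})

#' GLMResult: channelwise OLS estimates
#'
#' @slot beta P-by-C matrix of coefficients (one column per data column).
#' @slot sigma2 residual variance per data column.
#' @slot dof residual degrees of freedom (T - rank(X)).
#' @slot XtXinv (X'X)^-1 (generalized inverse if rank deficient).
#' @slot labels design column labels.
#' @slot columnNames names of the fitted data columns.
#' @export
setClass("GLMResult",
  representation(beta = "matrix", sigma2 = "numeric", dof = "numeric",
                 XtXinv = "matrix", labels = "character",
                 columnNames = "character"))

#' QCReport: channel-quality summary of a recording
#'
#' @slot channelTable data.frame with per-column metrics: \code{column},
#'   \code{variance}, \code{spikes}, \code{flatline_frac}, \code{missing_frac}.
#' @slot durationS recording duration in seconds.
#' @slot fs sampling rate in Hz.
#' @slot periodograms named list of (f, power) data.frames for the columns
#'   that were requested.
#' @export
setClass("QCReport",
  representation(channelTable = "data.frame", durationS = "numeric",
                 fs = "numeric", periodograms = "list"),
  prototype(periodograms = list()))

#' PipelineSpec: ordered, parameterised preprocessing steps
#'
#' @slot steps list of lists, each with \code{name} and \code{params}.
#' @slot chromophores chromophore subset the pipeline applies to
#'   (\code{character(0)} = all present).
#' @export
setClass("PipelineSpec",
  representation(steps = "list", chromophores = "character"),
  prototype(chromophores = character(0)))

setValidity("PipelineSpec", function(object) {
  bad <- vapply(object@steps, function(s)
    is.null(s$name) || !is.character(s$name), logical(1))
  if (any(bad)) "every step needs a character 'name'" else TRUE
})

#' ScenarioSpec: ground-truth generator parameters for synthetic recordings
#'
#' Describes a simulated multichannel hemoglobin recording: deterministic
#' polynomial trend, physiological oscillators (Mayer waves ~0.1 Hz,
#' respiration ~0.3 Hz, cardiac ~1 Hz, neural low-frequency bands), white
#' measurement noise, motion artifacts (spikes and baseline steps shared
#' across chromophores), a superficial component picked up by designated
#' short-separation channels, an optional task design with true effect sizes
#' and an optional true inter-channel covariance for connectivity scenarios.
#'
#' @slot nChannels number of measurement channels.
#' @slot fs sampling rate in Hz.
#' @slot durationS duration in seconds.
#' @slot seed RNG seed; the same spec and seed give bitwise-identical output.
#' @slot trend polynomial coefficients (intercept, linear, quadratic ...) of
#'   the deterministic drift, units of concentration per power of seconds.
#' @slot oscillators data.frame with columns \code{freq}, \code{amplitude},
#'   \code{phase}; shared deterministic physiology across channels.
#' @slot noiseSd standard deviation of white measurement noise.
#' @slot spikes data.frame with \code{time_s}, \code{amplitude},
#'   \code{channel} (NA = all channels).
#' @slot steps data.frame with \code{time_s}, \code{size}, \code{channel}.
#' @slot superficialWeight per-channel weight of the shared superficial
#'   (scalp) component; recycled.
#' @slot shortChannels integer ids of short-separation channels.
#' @slot hbrRatio scaling of the neural HbR signal relative to HbO
#'   (negative: anticorrelated, default -1/3).
#' @slot taskDesign a \code{TaskDesign} or NULL.
#' @slot betas true per-condition effect amplitudes.
#' @slot covariance true inter-channel covariance of the neural component
#'   (matrix) or NULL for independent channels.
#' @export
setClass("ScenarioSpec",
  representation(nChannels = "integer", fs = "numeric", durationS = "numeric",
                 seed = "integer", trend = "numeric", oscillators = "data.frame",
                 noiseSd = "numeric", spikes = "data.frame", steps = "data.frame",
                 superficialWeight = "numeric", shortChannels = "integer",
                 hbrRatio = "numeric", taskDesign = "ANY", betas = "numeric",
                 covariance = "ANY"),
  prototype(trend = c(0, 0), noiseSd = 0, superficialWeight = 0,
            shortChannels = integer(0), hbrRatio = -1/3, taskDesign = NULL,
            betas = numeric(0), covariance = NULL))

setValidity("ScenarioSpec", function(object) {
  msg <- character(0)
  if (object@nChannels < 1) msg <- c(msg, "need at least one channel")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be positive")
  if (length(msg)) msg else TRUE
})
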