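#' @include AllGenerics.R
NULL

#' Construct a NirsRecording
#'
#' @param data numeric matrix, time in rows. For \code{kind = "hb"} the
#'   columns must be chromophore blocks (all channels of chromophore 1, then
#'   all channels of chromophore 2, ...).
#' @param fs sampling rate in Hz.
#' @param kind signal kind: "intensity", "optical_density" or "hb".
#' @param chromophores chromophore labels for kind "hb" (default HbO, HbR).
#' @param wavelengths wavelengths in nm for intensity/OD recordings.
#' @param channels optional data.frame of channel metadata; a default table
#'   with sequential source/detector indices is built when omitted.
#' @param history list of processing records (normally left empty).
#' @return a validated \code{NirsRecording}.
#' @examples
#' rec <- NirsRecording(matrix(rnorm(40), 10, 4), fs = 10)
#' nChannels(rec)
#' @export
NirsRecording <- function(data, fs, kind = "hb",
                          chromophores = c("HbO", "HbR"),
                          wavelengths = numeric(0),
                          channels = NULL, history = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  dimnames(data) <- NULL
  nblk <- if (kind == "hb") length(chromophores) else max(length(wavelengths), 1L)
  if (ncol(data) %% nblk != 0)
    stop("column count (", ncol(data), ") not divisible by block count (", nblk, ")")
  nch <- ncol(data) %/% nblk
  if (is.null(channels)) channels <- defaultChannelTable(nch)
  new("NirsRecording", data = data, signalKind = kind,
      chromophores = if (kind == "hb") chromophores else character(0),
      wavelengths = wavelengths, fs = fs, channels = channels,
      history = history)
}

#' Default channel metadata table
#'
#' @param n number of channels.
#' @return data.frame with 1-based ids and placeholder source/detector pairs.
#' @export
defaultChannelTable <- function(n) {
  data.frame(id = seq_len(n), source_idx = seq_len(n),
             detector_idx = seq_len(n), is_short = FALSE)
}

#' @rdname accessors
#' @param x object
#' @export
setMethod("recData", "NirsRecording", function(x, ...) x@data)

#' @rdname accessors
#' @export
setMethod("samplingRate", "NirsRecording", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("signalKind", "NirsRecording", function(x) x@signalKind)

#' @rdname accessors
#' @export
setMethod("chromophores", "NirsRecording", function(x) x@chromophores)

#' @rdname accessors
#' @export
setMethod("channelInfo", "NirsRecording", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("nChannels", "NirsRecording", function(x) nrow(x@channels))

#' @rdname accessors
#' @export
setMethod("nTimepoints", "NirsRecording", function(x) nrow(x@data))

#' @rdname accessors
#' @export
setMethod("processingHistory", "NirsRecording", function(x) x@history)

#' @rdname chromData
#' @export
setMethod("chromData", "NirsRecording", function(x, which) {
  nch <- nChannels(x)
  if (x@signalKind == "hb") {
    k <- match(which, x@chromophores)
    if (is.na(k)) stop("chromophore '", which, "' not present")
  } else {
    k <- as.integer(which)
    if (k < 1 || k > max(length(x@wavelengths), 1L))
      stop("wavelength block ", which, " not present")
  }
  x@data[, (k - 1L) * nch + seq_len(nch), drop = FALSE]
})

# replace one chromophore block, returning a bare matrix update
.setChromBlock <- function(rec, which, value) {
  nch <- nChannels(rec)
  k <- match(which, rec@chromophores)
  rec@data[, (k - 1L) * nch + seq_len(nch)] <- value
  rec
}

# Recompute HbT from HbO + HbR if present (keeps the HbT invariant after
# steps that alter HbO/HbR independently).
.refreshHbT <- function(rec) {
  if (rec@signalKind == "hb" &&
      all(c("HbO", "HbR", "HbT") %in% rec@chromophores)) {
    rec <- .setChromBlock(rec, "HbT",
                          chromData(rec, "HbO") + chromData(rec, "HbR"))
  }
  rec
}

#' Append a processing record to a recording's history
#'
#' Every mutating operation calls this exactly once, so the history length
#' equals the number of steps applied.
#'
#' @param rec a \code{NirsRecording}.
#' @param name step name.
#' @param params named list of parameters used.
#' @return the recording with one extra history record.
#' @export
appendHistory <- function(rec, name, params = list()) {
  rec@history <- c(rec@history,
                   list(list(name = name, params = params,
                             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))))
  rec
}

setMethod("show", "NirsRecording", function(object) {
  cat(sprintf("NirsRecording: %d time points x %d columns (%s)\n",
              nrow(object@data), ncol(object@data), object@signalKind))
  cat(sprintf("  %d channels @ %.4g Hz, %.4g s\n", nChannels(object),
              object@fs, nrow(object@data) / object@fs))
  if (object@signalKind == "hb")
    cat("  chromophores:", paste(object@chromophores, collapse = ", "), "\n")
  else if (length(object@wavelengths))
    cat("  wavelengths:", paste(object@wavelengths, collapse = ", "), "nm\n")
  if (length(object@history))
    cat("  history:", paste(vapply(object@history, `[[`, "", "name"),
                            collapse = " -> "), "\n")
})
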