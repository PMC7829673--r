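#' @include methods-containers.R
NULL

# SNIRF stores dataTimeSeries as time x channel in C (h5py) order; rhdf5
# presents HDF5 dims reversed relative to that, so reads/writes transpose.

.snirfKindFromMeas <- function(ml) {
  dt <- vapply(ml, function(m) as.numeric(m$dataType[1]), numeric(1))
  if (all(dt < 100)) return("intensity")
  labels <- vapply(ml, function(m)
    if (is.null(m$dataTypeLabel)) "" else as.character(m$dataTypeLabel[1]), "")
  if (all(labels %in% c("HbO", "HbR", "HbT"))) return("hb")
  if (all(labels %in% c("dOD"))) return("optical_density")
  stop("unsupported mixture of SNIRF dataType codes/labels")
}

#' Read a SNIRF file
#'
#' Reads the first data block of a SNIRF (HDF5) container into a
#' \code{\link{NirsRecording}}. The signal kind is inferred from the SNIRF
#' data-type codes (raw CW amplitude, processed dOD, or processed hemoglobin
#' with HbO/HbR/HbT labels). The time vector must be uniform: relative
#' jitter beyond 1e-6 is rejected rather than silently resampled.
#'
#' @param path path to a .snirf file.
#' @return a \code{NirsRecording}.
#' @export
readSnirf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  top <- rhdf5::h5ls(path, recursive = 1)$name
  if (!"nirs" %in% top)
    stop("not a SNIRF file: missing required group /nirs")
  inNirs <- rhdf5::h5ls(path, recursive = 2)
  inNirs <- inNirs$name[inNirs$group == "/nirs"]
  if (!"data1" %in% inNirs)
    stop("invalid SNIRF file: missing required group /nirs/data1")
  raw <- rhdf5::h5read(path, "/nirs/data1")
  if (is.null(raw$dataTimeSeries))
    stop("invalid SNIRF file: missing dataset /nirs/data1/dataTimeSeries")
  data <- t(raw$dataTimeSeries)
  tv <- as.numeric(raw$time)
  if (length(tv) == 2 && nrow(data) > 2) {
    fs <- 1 / tv[2]
  } else {
    dt <- diff(tv)
    if (length(dt) == 0) stop("SNIRF time vector too short")
    jitter <- (max(dt) - min(dt)) / mean(dt)
    if (!is.finite(jitter) || jitter > 1e-6)
      stop("nonuniform SNIRF time vector (relative jitter ",
           format(jitter, digits = 3), " > 1e-6); resample externally first")
    fs <- 1 / mean(dt)
  }
  mlNames <- grep("^measurementList[0-9]+$", names(raw), value = TRUE)
  mlNames <- mlNames[order(as.integer(sub("measurementList", "", mlNames)))]
  ml <- raw[mlNames]
  if (length(ml) != ncol(data))
    stop("SNIRF measurementList count (", length(ml),
         ") does not match data columns (", ncol(data), ")")
  kind <- .snirfKindFromMeas(ml)
  src <- vapply(ml, function(m) as.integer(m$sourceIndex[1]), 1L)
  det <- vapply(ml, function(m) as.integer(m$detectorIndex[1]), 1L)
  pairKey <- paste(src, det)
  uniq <- !duplicated(pairKey)
  pairIds <- match(pairKey, pairKey[uniq])
  nch <- sum(uniq)
  probe <- if ("probe" %in% inNirs) rhdf5::h5read(path, "/nirs/probe") else NULL
  if (kind == "hb") {
    labels <- vapply(ml, function(m) as.character(m$dataTypeLabel[1]), "")
    chroms <- intersect(.CHROMOPHORES, unique(labels))
    blk <- match(labels, chroms)
    wavelengths <- numeric(0)
  } else {
    wl <- vapply(ml, function(m) as.integer(m$wavelengthIndex[1]), 1L)
    blk <- wl
    chroms <- character(0)
    wavelengths <- if (!is.null(probe$wavelengths)) as.numeric(probe$wavelengths)
                   else sort(unique(wl))
  }
  # reorder columns into block-major, channel-minor canonical layout
  ord <- order(blk, pairIds)
  data <- data[, ord, drop = FALSE]
  channels <- data.frame(id = seq_len(nch),
                         source_idx = src[uniq], detector_idx = det[uniq],
                         is_short = FALSE)
  if (!is.null(probe) && !is.null(probe$sourcePos3D)) {
    sp <- t(probe$sourcePos3D); dp <- t(probe$detectorPos3D)
    mid <- (sp[channels$source_idx, , drop = FALSE] +
            dp[channels$detector_idx, , drop = FALSE]) / 2
    channels$mni_x <- mid[, 1]; channels$mni_y <- mid[, 2]
    channels$mni_z <- mid[, 3]
  }
  NirsRecording(data, fs = fs, kind = kind, chromophores = chroms,
                wavelengths = wavelengths, channels = channels)
}

#' Write a SNIRF file
#'
#' Serialises a \code{NirsRecording} to the SNIRF (HDF5) layout:
#' \code{/nirs/data1/dataTimeSeries} with a compact \code{[start, dt]} time
#' vector, one \code{measurementList} group per column (processed hemoglobin
#' columns carry dataType 99999 with HbO/HbR/HbT dataTypeLabel; raw
#' intensity carries dataType 1 with a wavelength index), and a minimal
#' \code{/nirs/probe} group.
#'
#' @param rec a \code{NirsRecording}.
#' @param path output path (.snirf).
#' @return \code{path}, invisibly.
#' @export
writeSnirf <- function(rec, path) {
  stopifnot(is(rec, "NirsRecording"))
  if (nChannels(rec) == 0) stop("cannot write a recording with no channels")
  validObject(rec)
  if (file.exists(path)) file.remove(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  h5f <- path
  rhdf5::h5write("1.0", h5f, "formatVersion")
  rhdf5::h5createGroup(h5f, "nirs")
  rhdf5::h5createGroup(h5f, "nirs/metaDataTags")
  meta <- c(SubjectID = "unknown", MeasurementDate = "unknown",
            MeasurementTime = "unknown", LengthUnit = "mm",
            TimeUnit = "s", FrequencyUnit = "Hz")
  for (nm in names(meta))
    rhdf5::h5write(unname(meta[nm]), h5f, paste0("nirs/metaDataTags/", nm))
  rhdf5::h5createGroup(h5f, "nirs/data1")
  rhdf5::h5write(t(recData(rec)), h5f, "nirs/data1/dataTimeSeries")
  rhdf5::h5write(c(0, 1 / samplingRate(rec)), h5f, "nirs/data1/time")
  ch <- channelInfo(rec)
  nch <- nrow(ch)
  if (rec@signalKind == "hb") {
    blocks <- rec@chromophores
    for (k in seq_along(blocks)) for (i in seq_len(nch)) {
      g <- sprintf("nirs/data1/measurementList%d", (k - 1L) * nch + i)
      rhdf5::h5createGroup(h5f, g)
      rhdf5::h5write(as.integer(ch$source_idx[i]), h5f, paste0(g, "/sourceIndex"))
      rhdf5::h5write(as.integer(ch$detector_idx[i]), h5f, paste0(g, "/detectorIndex"))
      rhdf5::h5write(99999L, h5f, paste0(g, "/dataType"))
      rhdf5::h5write(blocks[k], h5f, paste0(g, "/dataTypeLabel"))
      rhdf5::h5write(1L, h5f, paste0(g, "/dataTypeIndex"))
    }
    wl <- if (length(rec@wavelengths)) rec@wavelengths else c(760, 850)
  } else {
    nw <- max(length(rec@wavelengths), 1L)
    isOD <- rec@signalKind == "optical_density"
    for (k in seq_len(nw)) for (i in seq_len(nch)) {
      g <- sprintf("nirs/data1/measurementList%d", (k - 1L) * nch + i)
      rhdf5::h5createGroup(h5f, g)
      rhdf5::h5write(as.integer(ch$source_idx[i]), h5f, paste0(g, "/sourceIndex"))
      rhdf5::h5write(as.integer(ch$detector_idx[i]), h5f, paste0(g, "/detectorIndex"))
      rhdf5::h5write(if (isOD) 99999L else 1L, h5f, paste0(g, "/dataType"))
      if (isOD) rhdf5::h5write("dOD", h5f, paste0(g, "/dataTypeLabel"))
      rhdf5::h5write(as.integer(k), h5f, paste0(g, "/wavelengthIndex"))
      rhdf5::h5write(1L, h5f, paste0(g, "/dataTypeIndex"))
    }
    wl <- rec@wavelengths
  }
  rhdf5::h5createGroup(h5f, "nirs/probe")
  rhdf5::h5write(as.numeric(wl), h5f, "nirs/probe/wavelengths")
  nSrc <- max(ch$source_idx); nDet <- max(ch$detector_idx)
  if (all(c("mni_x", "mni_y", "mni_z") %in% names(ch))) {
    sp <- matrix(0, nSrc, 3); dp <- matrix(0, nDet, 3)
    for (i in seq_len(nch)) {
      sp[ch$source_idx[i], ] <- c(ch$mni_x[i], ch$mni_y[i], ch$mni_z[i])
      dp[ch$detector_idx[i], ] <- c(ch$mni_x[i], ch$mni_y[i], ch$mni_z[i])
    }
    rhdf5::h5write(t(sp), h5f, "nirs/probe/sourcePos3D")
    rhdf5::h5write(t(dp), h5f, "nirs/probe/detectorPos3D")
  } else {
    rhdf5::h5write(t(matrix(0, nSrc, 2)), h5f, "nirs/probe/sourcePos2D")
    rhdf5::h5write(t(matrix(0, nDet, 2)), h5f, "nirs/probe/detectorPos2D")
  }
  invisible(path)
}
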