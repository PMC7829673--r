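#' @include io-snirf.R
NULL

#' Read a manual-input CSV time series
#'
#' Reads the documented plain-text dialect for hemoglobin or optical-density
#' time series: comma-separated, '.' decimal, UTF-8, one header row of
#' channel labels, one row per time point. Columns are chromophore blocks
#' (all HbO channels, then all HbR channels); HbT is never stored, it is
#' derived on demand. Cells reading \code{NaN} or \code{NA} are accepted and
#' stored as missing; their count is recorded in the recording's history and
#' surfaces in \code{\link{qcSummary}}.
#'
#' @param path CSV path.
#' @param fs sampling rate in Hz (the file stores no time axis).
#' @param kind "hb" or "optical_density".
#' @param chromophores chromophore block labels for kind "hb".
#' @return a \code{NirsRecording}.
#' @export
readManualCsv <- function(path, fs, kind = "hb",
                          chromophores = c("HbO", "HbR")) {
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) != 1)
    stop("ragged CSV: rows have differing field counts (",
         paste(unique(nf), collapse = ", "), ")")
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df)
  if (is.character(m)) {
    suppressWarnings(num <- matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- is.na(num) & !(trimws(m) %in% c("NaN", "NA", "nan", ""))
    if (any(bad))
      stop("non-numeric cells at rows ",
           paste(utils::head(which(rowSums(bad) > 0), 5), collapse = ", "))
    m <- num
  }
  nblk <- if (kind == "hb") length(chromophores) else 1L
  if (ncol(m) %% nblk != 0)
    stop("column count not divisible by chromophore count (",
         ncol(m), " columns, ", nblk, " chromophores)")
  nMissing <- sum(is.na(m))
  rec <- NirsRecording(m, fs = fs, kind = kind, chromophores = chromophores)
  appendHistory(rec, "read_csv_manual",
                list(path = basename(path), n_missing = nMissing))
}

#' Write a recording to the manual CSV dialect
#'
#' @param rec a \code{NirsRecording} (kind "hb" or "optical_density"); HbT is
#'   dropped on writing, per the dialect.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeManualCsv <- function(rec, path) {
  stopifnot(is(rec, "NirsRecording"))
  if (rec@signalKind == "hb") {
    keep <- setdiff(rec@chromophores, "HbT")
    m <- do.call(cbind, lapply(keep, function(cc) chromData(rec, cc)))
    labels <- as.vector(t(outer(keep, seq_len(nChannels(rec)),
                                function(a, b) sprintf("CH%d_%s", b, a))))
  } else {
    m <- recData(rec)
    labels <- sprintf("COL%d", seq_len(ncol(m)))
  }
  colnames(m) <- labels
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a probe setup
#'
#' Probe geometry is stored as JSON text:
#' \code{{"sources": [{"label","x","y"}...], "detectors": [...],
#' "pairs": [[s,d],...]}}.
#'
#' @param path JSON file path.
#' @return a \code{ProbeSetup}.
#' @export
readProbeSetup <- function(path) {
  j <- jsonlite::fromJSON(path)
  pairs <- matrix(as.integer(as.matrix(j$pairs)), ncol = 2)
  ProbeSetup(as.data.frame(j$sources), as.data.frame(j$detectors), pairs)
}

#' @rdname readProbeSetup
#' @param probe a \code{ProbeSetup}.
#' @export
writeProbeSetup <- function(probe, path) {
  j <- list(sources = probe@sources, detectors = probe@detectors,
            pairs = unname(as.matrix(probe@pairs)))
  writeLines(jsonlite::toJSON(j, digits = NA, auto_unbox = FALSE), path)
  invisible(path)
}

#' Standard probe geometries
#'
#' Builds the common rectangular optode grids used in fNIRS (e.g. "3x5":
#' three rows by five columns of alternating sources and detectors, giving 22
#' measurement channels at the horizontally/vertically adjacent pairs).
#'
#' @param layout one of "3x3", "3x5", "4x4", "3x11".
#' @param spacing optode spacing in arbitrary planar units.
#' @param offset (x, y) offset added to every optode, for multi-probe montages.
#' @return a \code{ProbeSetup}.
#' @export
standardProbe <- function(layout = "3x5", spacing = 30, offset = c(0, 0)) {
  dims <- as.integer(strsplit(layout, "x")[[1]])
  if (length(dims) != 2 || any(is.na(dims)))
    stop("unknown layout: ", layout)
  nr <- dims[1]; nc <- dims[2]
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  isSource <- (grid$row + grid$col) %% 2 == 0
  pos <- data.frame(x = (grid$col - 1) * spacing + offset[1],
                    y = (nr - grid$row) * spacing + offset[2])
  optode <- integer(nrow(grid))   # index within its own role
  optode[isSource] <- seq_len(sum(isSource))
  optode[!isSource] <- seq_len(sum(!isSource))
  sources <- data.frame(label = sprintf("S%d", optode[isSource]),
                        x = pos$x[isSource], y = pos$y[isSource])
  detectors <- data.frame(label = sprintf("D%d", optode[!isSource]),
                          x = pos$x[!isSource], y = pos$y[!isSource])
  pairs <- NULL
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      adjacent <- (abs(grid$row[i] - grid$row[j]) +
                   abs(grid$col[i] - grid$col[j])) == 1
      if (adjacent && isSource[i] && !isSource[j])
        pairs <- rbind(pairs, c(optode[i], optode[j]))
    }
  }
  pairs <- unique(pairs)
  ProbeSetup(sources, detectors, pairs)
}

#' Channel metadata from a probe setup
#'
#' @param probe a \code{ProbeSetup}.
#' @return data.frame suitable for the \code{channels} slot of a recording;
#'   channel layout coordinates are source-detector midpoints.
#' @export
probeChannelTable <- function(probe) {
  n <- nrow(probe@pairs)
  sx <- probe@sources$x[probe@pairs[, 1]]
  sy <- probe@sources$y[probe@pairs[, 1]]
  dx <- probe@detectors$x[probe@pairs[, 2]]
  dy <- probe@detectors$y[probe@pairs[, 2]]
  data.frame(id = seq_len(n), source_idx = probe@pairs[, 1],
             detector_idx = probe@pairs[, 2],
             x = (sx + dx) / 2, y = (sy + dy) / 2, is_short = FALSE)
}

#' Read / write a task design
#'
#' Task designs are tab-separated text with columns \code{condition},
#' \code{onset_s}, \code{duration_s}.
#'
#' @param path TSV path.
#' @return a \code{TaskDesign}.
#' @export
readTaskDesign <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "onset_s", "duration_s")
  if (!all(need %in% names(df)))
    stop("task design needs columns: ", paste(need, collapse = ", "))
  TaskDesign(df[, need])
}

#' @rdname readTaskDesign
#' @param design a \code{TaskDesign}.
#' @export
writeTaskDesign <- function(design, path) {
  utils::write.table(design@conditions, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export a connectivity matrix as connectome-viewer node/edge files
#'
#' Writes \code{<prefix>.node} (one line per channel:
#' \code{x y z color size label}) and \code{<prefix>.edge} (full symmetric
#' matrix, whitespace-delimited), the plain-text convention of common brain
#' connectome viewers.
#'
#' @param cm a \code{ConnectivityMatrix}.
#' @param coords matrix/data.frame of per-channel MNI coordinates (C x 3).
#' @param pathPrefix output path without extension.
#' @param color,size node display attributes, recycled per channel.
#' @return character vector of the two file paths, invisibly.
#' @export
exportNodeEdge <- function(cm, coords, pathPrefix, color = 1, size = 1) {
  v <- fcValues(cm)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(v))
    stop("coordinate count (", nrow(coords),
         ") does not match channel count (", nrow(v), ")")
  nodeFile <- paste0(pathPrefix, ".node")
  edgeFile <- paste0(pathPrefix, ".edge")
  node <- data.frame(coords[, 1], coords[, 2], coords[, 3],
                     rep_len(color, nrow(v)), rep_len(size, nrow(v)),
                     sprintf("CH%d", cm@channelIds))
  utils::write.table(node, nodeFile, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                     edgeFile, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(c(nodeFile, edgeFile))
}

#' Export a (thresholded) connectivity matrix as a plain-text square matrix
#'
#' The output is the whitespace-delimited square matrix format consumed by
#' graph-metric toolkits.
#'
#' @param cm a \code{ConnectivityMatrix} or a symmetric numeric matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(cm, path) {
  v <- if (is(cm, "ConnectivityMatrix")) fcValues(cm) else as.matrix(cm)
  if (nrow(v) != ncol(v) || any(abs(v - t(v)) > 1e-12, na.rm = TRUE))
    stop("network export requires a symmetric square matrix")
  utils::write.table(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a plain-text square matrix (edge / network file)
#'
#' @param path path to a whitespace-delimited numeric matrix.
#' @return numeric matrix.
#' @export
readNetworkMatrix <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Read a per-channel MNI coordinate table
#'
#' Tab- or comma-separated text with columns \code{channel}, \code{x},
#' \code{y}, \code{z} (mm, MNI space). Registration itself is out of scope:
#' coordinates come precomputed.
#'
#' @param path file path.
#' @return data.frame ordered by channel id.
#' @export
readMniCoordinates <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  df[order(df$channel), ]
}
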