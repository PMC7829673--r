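#' @include pipeline-spec.R
NULL

#' One-sided amplitude spectrum
#'
#' Decomposes a real series into a DC term plus cosine components,
#' \deqn{x(t) = a_0 + \sum_k A_k \cos(2\pi f_k t - \phi_k),}
#' at the Fourier frequencies \eqn{f_k = k f_s / N}, \eqn{k = 1..\lfloor N/2
#' \rfloor}. Amplitudes are \eqn{A_k = 2 |X_k| / N} (the Nyquist bin, when N
#' is even, carries \eqn{|X_k| / N}); \eqn{a_0} is the signal mean; phases
#' are quadrant-corrected \eqn{\phi_k = \mathrm{atan2}(b_k, a_k)}.
#'
#' @param x numeric vector, length >= 4.
#' @param fs sampling rate in Hz.
#' @return a \code{\link{SpectrumResult}}.
#' @examples
#' t <- seq(0, 99.9, by = 0.1)
#' sp <- amplitudeSpectrum(3 * cos(2 * pi * 0.05 * t), fs = 10)
#' @export
amplitudeSpectrum <- function(x, fs) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 4) stop("need at least 4 time points")
  X <- stats::fft(x)
  kmax <- N %/% 2
  k <- seq_len(kmax)
  ak <- 2 * Re(X[k + 1]) / N
  bk <- -2 * Im(X[k + 1]) / N
  Ak <- sqrt(ak^2 + bk^2)
  if (N %% 2 == 0) Ak[kmax] <- Ak[kmax] / 2   # Nyquist bin: |X|/N
  phik <- atan2(bk, ak)
  new("SpectrumResult", fk = k * fs / N, Ak = Ak, phik = phik,
      a0 = mean(x), N = as.integer(N), fs = fs)
}

#' Mean square of the signal implied by a spectrum (Parseval)
#'
#' \eqn{a_0^2 + \sum A_k^2/2} with the Nyquist term (even N) contributing
#' \eqn{A^2} rather than \eqn{A^2/2}. Used as the spectrum's energy
#' invariant.
#'
#' @param sp a \code{SpectrumResult}.
#' @return scalar mean-square value.
#' @export
spectrumMeanSquare <- function(sp) {
  Ak2 <- sp@Ak^2 / 2
  if (sp@N %% 2 == 0) {
    last <- length(Ak2)
    Ak2[last] <- sp@Ak[last]^2
  }
  sp@a0^2 + sum(Ak2)
}

#' Amplitude of low-frequency fluctuation (ALFF, fALFF) per channel
#'
#' For each channel the amplitude spectrum is computed and
#' \deqn{ALFF = \frac{1}{N_k} \sum_{k: f_k \in [f_{lo}, f_{hi}]} A_k}
#' (band-inclusive), while fALFF is the ratio of the in-band amplitude sum
#' to the total over the whole one-sided spectrum (DC excluded from both).
#' zALFF and zfALFF standardise each index across channels by subtracting
#' the global mean and dividing by the population (divide-by-C) standard
#' deviation. fALFF is only meaningful on data whose full spectrum was
#' preserved (unfiltered or wide-band); on band-limited input it tends to 1.
#'
#' @param rec a \code{NirsRecording} (kind "hb") or a T x C numeric matrix.
#' @param band analysis band in Hz, default c(0.01, 0.08).
#' @param chromophore chromophore to analyse when \code{rec} is a recording.
#' @param mask optional logical per channel; z-scores are computed across
#'   in-mask channels only.
#' @return an \code{\link{ALFFResult}}.
#' @export
computeALFF <- function(rec, band = c(0.01, 0.08), chromophore = "HbO",
                        mask = NULL) {
  m <- if (is(rec, "NirsRecording")) chromData(rec, chromophore)
       else as.matrix(rec)
  fs <- if (is(rec, "NirsRecording")) samplingRate(rec)
        else attr(rec, "fs") %||% stop("matrix input needs attr(rec,'fs')")
  if (band[1] <= 0 || band[2] >= fs / 2 || diff(band) <= 0)
    stop("band must lie inside (0, fs/2) and be increasing")
  C <- ncol(m)
  alff <- falff <- rep(NA_real_, C)
  Nk <- NA_integer_
  for (j in seq_len(C)) {
    sp <- amplitudeSpectrum(m[, j], fs)
    inBand <- sp@fk >= band[1] & sp@fk <= band[2]
    if (!any(inBand)) stop("no frequency bins inside the band")
    Nk <- sum(inBand)
    alff[j] <- mean(sp@Ak[inBand])
    tot <- sum(sp@Ak)
    falff[j] <- if (tot > 0) sum(sp@Ak[inBand]) / tot else NA_real_
  }
  if (is.null(mask)) mask <- rep(TRUE, C)
  zalff <- .zScorePop(alff, mask)
  zfalff <- .zScorePop(falff, mask)
  new("ALFFResult",
      table = data.frame(channel = seq_len(C), alff = alff, falff = falff,
                         zalff = zalff, zfalff = zfalff),
      band = band, Nk = as.integer(Nk))
}

# population-sd z-score within mask; sd = 0 flagged with an error
.zScorePop <- function(v, mask) {
  z <- rep(NA_real_, length(v))
  vm <- v[mask & !is.na(v)]
  if (!length(vm)) return(z)
  sdp <- sqrt(mean((vm - mean(vm))^2))
  if (sdp == 0)
    stop("z-standardisation undefined: all in-mask channels identical (sd = 0)")
  z[mask & !is.na(v)] <- (vm - mean(vm)) / sdp
  z
}

#' Write a per-subject resting index table
#'
#' @param res an \code{ALFFResult}.
#' @param path TSV output path.
#' @return \code{path}, invisibly.
#' @export
writeAlffTable <- function(res, path) {
  utils::write.table(res@table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Functional connectivity matrix
#'
#' Pearson correlation of channel time series (whole-brain mode), of
#' ROI-mean time series (roi2roi), or of one seed-ROI mean against every
#' channel (roi2whole). ROI series are unweighted means of their member
#' channels, averaged before correlating. Zero-variance channels yield NA
#' correlations with a warning.
#'
#' @param rec a \code{NirsRecording} or T x C matrix.
#' @param chromophore chromophore to use when \code{rec} is a recording.
#' @param mode "wholebrain", "roi2roi" or "roi2whole".
#' @param roiSets for ROI modes: a list of integer channel-id vectors (the
#'   first entry is the seed in roi2whole mode).
#' @param fisherZ apply the Fisher transform z = arctanh(r); recommended
#'   before group-level tests.
#' @return a \code{\link{ConnectivityMatrix}}.
#' @export
fcMatrix <- function(rec, chromophore = "HbO",
                     mode = c("wholebrain", "roi2roi", "roi2whole"),
                     roiSets = NULL, fisherZ = FALSE) {
  mode <- match.arg(mode)
  m <- if (is(rec, "NirsRecording")) chromData(rec, chromophore)
       else as.matrix(rec)
  if (ncol(m) < 2 && mode == "wholebrain")
    stop("need at least 2 channels")
  if (mode != "wholebrain") {
    if (is.null(roiSets) || !length(roiSets) ||
        any(!vapply(roiSets, length, 1L)))
      stop("ROI modes need nonempty roiSets")
    roiSeries <- vapply(roiSets, function(ids) rowMeans(m[, ids, drop = FALSE]),
                        numeric(nrow(m)))
  }
  zeroVar <- apply(m, 2, stats::sd) == 0
  if (any(zeroVar))
    warning("zero-variance channel(s): ",
            paste(which(zeroVar), collapse = ", "), "; correlations set NA")
  vals <- switch(mode,
    wholebrain = suppressWarnings(stats::cor(m)),
    roi2roi = suppressWarnings(stats::cor(roiSeries)),
    roi2whole = {
      r <- suppressWarnings(stats::cor(roiSeries[, 1], m))
      matrix(r, nrow = 1)
    })
  if (any(zeroVar)) {
    if (mode == "wholebrain") { vals[zeroVar, ] <- NA; vals[, zeroVar] <- NA }
    if (mode == "roi2whole") vals[, zeroVar] <- NA
  }
  ids <- if (mode == "roi2roi") seq_along(roiSets) else seq_len(ncol(m))
  if (fisherZ) {
    vals <- atanh(pmin(pmax(vals, -1), 1))
    if (mode != "roi2whole") diag(vals) <- Inf
  }
  new("ConnectivityMatrix", values = vals, mode = mode,
      channelIds = as.integer(ids), fisherZ = fisherZ,
      thresholdState = list(method = "none"))
}

#' Threshold a connectivity matrix
#'
#' \strong{absolute}: keep entries strictly greater than \code{tau}, zero
#' the rest (the diagonal is untouched). \strong{sparsity}: keep the
#' \code{floor(s * C(C-1)/2)} largest off-diagonal upper-triangle values;
#' ties at the cutoff are all kept and the attained edge fraction is
#' reported in the threshold state. The result stays symmetric.
#'
#' @param cm an unthresholded \code{ConnectivityMatrix}.
#' @param method "absolute" or "sparsity".
#' @param value threshold tau (absolute) or target sparsity s in (0, 1].
#' @return the thresholded \code{ConnectivityMatrix}.
#' @export
thresholdMatrix <- function(cm, method = c("absolute", "sparsity"), value) {
  method <- match.arg(method)
  if (!identical(cm@thresholdState$method, "none"))
    stop("matrix is already thresholded")
  v <- cm@values
  if (nrow(v) != ncol(v)) stop("only square matrices can be thresholded")
  C <- nrow(v)
  if (method == "absolute") {
    keep <- v > value
    diag(keep) <- TRUE
    v[!keep] <- 0
    attained <- sum(keep[upper.tri(keep)]) / (C * (C - 1) / 2)
    state <- list(method = "absolute", value = value, attained = attained)
  } else {
    if (value <= 0 || value > 1) stop("sparsity must lie in (0, 1]")
    ut <- v[upper.tri(v)]
    nKeep <- floor(value * length(ut))
    if (nKeep >= length(ut)) {
      state <- list(method = "sparsity", value = value, attained = 1)
    } else if (nKeep == 0) {
      v[upper.tri(v) | lower.tri(v)] <- 0
      state <- list(method = "sparsity", value = value, attained = 0)
    } else {
      cutoff <- sort(ut, decreasing = TRUE)[nKeep]
      mask <- matrix(FALSE, C, C)
      mask[upper.tri(mask)] <- ut >= cutoff    # ties at the cutoff all kept
      mask <- mask | t(mask)
      diag(mask) <- TRUE
      v[!mask] <- 0
      state <- list(method = "sparsity", value = value,
                    attained = sum(mask[upper.tri(mask)]) / length(ut))
    }
  }
  initialize(cm, values = v, thresholdState = state)
}
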