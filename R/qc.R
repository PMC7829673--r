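#' @include groupstats.R
NULL

#' Periodogram of a series
#'
#' Squared-amplitude spectrum derived from \code{\link{amplitudeSpectrum}}:
#' \eqn{P_k = A_k^2 / 2} per frequency bin, DC excluded. Shares the spectrum
#' code path, so an on-bin sinusoid of amplitude A shows power A^2/2 at its
#' bin.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @return data.frame with columns \code{f} (Hz) and \code{power}.
#' @export
channelPeriodogram <- function(x, fs) {
  sp <- amplitudeSpectrum(x, fs)
  data.frame(f = sp@fk, power = sp@Ak^2 / 2)
}

#' Channel-quality summary of a recording
#'
#' Computes per-column metrics supporting inclusion/exclusion decisions:
#' variance, spike count, flatline fraction (fraction of samples whose
#' successor is identical), and missing fraction. A spike is a sample whose
#' temporal derivative exceeds \code{spikeK} robust standard deviations
#' (1.4826*MAD of the differenced series) in both directions — a large
#' excursion immediately reversed — which keeps the count robust to
#' baseline steps and slow drifts. Metrics are deterministic and invariant
#' to channel ordering.
#'
#' @param rec a \code{NirsRecording}.
#' @param spikeK spike threshold in MAD-based robust SDs (default 5).
#' @param periodogramColumns optional integer column indices for which
#'   periodograms are attached to the report.
#' @return a \code{\link{QCReport}}.
#' @export
qcSummary <- function(rec, spikeK = 5, periodogramColumns = integer(0)) {
  stopifnot(is(rec, "NirsRecording"))
  m <- recData(rec)
  T <- nrow(m)
  met <- t(apply(m, 2, function(x) {
    miss <- mean(is.na(x))
    xo <- x[!is.na(x)]
    if (length(xo) < 2)
      return(c(variance = NA, spikes = 0, flat = 0, missing = miss))
    d <- diff(xo)
    dmd <- stats::median(d)
    s <- stats::mad(d)             # 1.4826 * MAD of the derivative
    spikes <- if (s > 0) {
      big <- abs(d - dmd) > spikeK * s
      rev <- big[-length(big)] & big[-1] &
        (sign(d[-length(d)] - dmd) != sign(d[-1] - dmd))
      sum(rev)
    } else 0
    flat <- sum(diff(xo) == 0) / (length(xo) - 1)
    c(variance = stats::var(xo), spikes = spikes, flat = flat, missing = miss)
  }))
  tab <- data.frame(column = seq_len(ncol(m)), variance = met[, 1],
                    spikes = as.integer(met[, 2]), flatline_frac = met[, 3],
                    missing_frac = met[, 4])
  pg <- list()
  for (j in periodogramColumns)
    pg[[as.character(j)]] <- channelPeriodogram(m[, j], samplingRate(rec))
  new("QCReport", channelTable = tab, durationS = T / samplingRate(rec),
      fs = samplingRate(rec), periodograms = pg)
}

#' Write a QC report as TSV
#'
#' @param report a \code{QCReport}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeQcReport <- function(report, path) {
  utils::write.table(report@channelTable, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Task reference signals and their periodograms
#'
#' HRF-convolved boxcar per selected condition (the same columns a GLM
#' design would contain), for overlaying on the data during quality
#' control.
#'
#' @param design a \code{TaskDesign}.
#' @param T number of time points.
#' @param fs sampling rate in Hz.
#' @param conditions condition names to include (default: all).
#' @return named list per condition: \code{list(series, periodogram)}.
#' @export
taskReference <- function(design, T, fs, conditions = NULL) {
  all <- unique(design@conditions$condition)
  if (is.null(conditions)) conditions <- all
  conditions <- intersect(conditions, all)
  if (!length(conditions)) return(list())
  dm <- buildDesign(design, T, fs)
  out <- list()
  for (cond in conditions) {
    s <- dm@X[, match(cond, dm@labels)]
    out[[cond]] <- list(series = s, periodogram = channelPeriodogram(s, fs))
  }
  out
}
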