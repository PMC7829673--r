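#' @include filters.R
NULL

#' Trim initial and/or final time periods
#'
#' Drops \code{round(dropStartS * fs)} samples from the start and
#' \code{round(dropEndS * fs)} from the end. When a task design is supplied
#' its onsets are shifted by \code{-dropStartS}; events falling before time
#' zero are dropped with a warning.
#'
#' @param rec a \code{NirsRecording}.
#' @param dropStartS,dropEndS seconds to discard at each end.
#' @param design optional \code{TaskDesign} to shift along.
#' @return the trimmed recording, or \code{list(recording, design)} when a
#'   design was supplied.
#' @export
trimRecording <- function(rec, dropStartS = 0, dropEndS = 0, design = NULL) {
  fs <- samplingRate(rec)
  n0 <- round(dropStartS * fs)
  n1 <- round(dropEndS * fs)
  T <- nTimepoints(rec)
  if (n0 + n1 >= T - 1)
    stop("trimming ", dropStartS, " + ", dropEndS,
         " s leaves nothing of a ", T / fs, " s recording")
  rec@data <- rec@data[(n0 + 1):(T - n1), , drop = FALSE]
  rec <- appendHistory(rec, "trim",
                       list(drop_start_s = dropStartS, drop_end_s = dropEndS))
  if (is.null(design)) return(rec)
  cc <- design@conditions
  cc$onset_s <- cc$onset_s - dropStartS
  lost <- cc$onset_s < 0
  if (any(lost)) {
    warning(sum(lost), " event(s) fell before the trimmed origin and were dropped")
    cc <- cc[!lost, , drop = FALSE]
  }
  list(recording = rec,
       design = TaskDesign(cc, if (ncol(design@covariates)) design@covariates,
                           design@perSubject))
}

# polynomial detrend of a matrix; time axis normalized to [-1, 1]
.detrendMatrix <- function(m, order) {
  T <- nrow(m)
  tn <- if (T > 1) seq(-1, 1, length.out = T) else 0
  X <- stats::poly(tn, degree = max(order, 1), raw = FALSE, simple = TRUE)
  X <- cbind(1, X[, seq_len(order), drop = FALSE])
  if (order == 0) X <- matrix(1, T, 1)
  fit <- stats::lm.fit(X, m)
  m - X %*% fit$coefficients
}

#' Polynomial detrending
#'
#' Fits and subtracts a least-squares polynomial of the given order per
#' column (including the intercept, so the output columns have zero mean).
#' The fit uses an orthogonal polynomial basis on a time axis normalised to
#' [-1, 1] for numerical conditioning. Order 1 (linear, the default) removes
#' slow instrumental and physiological drifts.
#'
#' @param rec a \code{NirsRecording} (or numeric matrix).
#' @param order polynomial order, >= 0 (0 = mean removal).
#' @return detrended object of the same type.
#' @export
detrendRecording <- function(rec, order = 1) {
  if (!is(rec, "NirsRecording")) return(.detrendMatrix(as.matrix(rec), order))
  if (order < 0) stop("order must be >= 0")
  if (nTimepoints(rec) <= order + 1)
    stop("polynomial order ", order, " needs more than ", order + 1,
         " time points")
  rec@data <- .detrendMatrix(rec@data, order)
  rec <- .refreshHbT(rec)
  appendHistory(rec, "detrend", list(order = order))
}

#' Motion correction by correlation-based signal improvement (CBSI)
#'
#' Exploits the physiological anticorrelation of HbO and HbR: the neural
#' component is negatively correlated across the two chromophores while
#' motion artifacts move them together. Per channel, with
#' \eqn{\alpha = sd(HbO)/sd(HbR)}:
#' \deqn{HbO' = (HbO - \alpha HbR)/2, \qquad HbR' = -HbO'/\alpha.}
#' By construction \eqn{cor(HbO', HbR') = -1}, and a pure common-mode
#' artifact (HbO = HbR) is annihilated. Channels with zero HbR variance are
#' skipped with a warning. HbT, if carried, is recomputed.
#'
#' @param rec a \code{NirsRecording} of kind "hb" with both HbO and HbR.
#' @return the corrected recording.
#' @export
motionCorrectCBSI <- function(rec) {
  stopifnot(is(rec, "NirsRecording"))
  if (!all(c("HbO", "HbR") %in% rec@chromophores))
    stop("CBSI needs both HbO and HbR")
  hbo <- chromData(rec, "HbO")
  hbr <- chromData(rec, "HbR")
  skipped <- integer(0)
  for (i in seq_len(ncol(hbo))) {
    sdr <- stats::sd(hbr[, i])
    if (!is.finite(sdr) || sdr == 0) { skipped <- c(skipped, i); next }
    alpha <- stats::sd(hbo[, i]) / sdr
    h <- (hbo[, i] - alpha * hbr[, i]) / 2
    hbo[, i] <- h
    hbr[, i] <- if (alpha > 0) -h / alpha else -h
  }
  if (length(skipped))
    warning("CBSI skipped channel(s) with zero HbR variance: ",
            paste(skipped, collapse = ", "))
  rec <- .setChromBlock(rec, "HbO", hbo)
  rec <- .setChromBlock(rec, "HbR", hbr)
  rec <- .refreshHbT(rec)
  appendHistory(rec, "cbsi", list(skipped = skipped))
}

# TDDR core for one column
.tddrColumn <- function(x, fs) {
  if (fs > 1) {
    bt <- signal::butter(3, 0.5 / (fs / 2), type = "low")
    low <- .filtfiltPad(bt$b, bt$a, x)
  } else {
    low <- x          # 0.5 Hz split impossible at fs <= 1 Hz
  }
  high <- x - low
  d <- diff(low)
  if (all(d == 0)) return(x)
  w <- rep(1, length(d))
  tune <- 4.685
  mu <- 0
  for (iter in seq_len(50)) {
    mu <- sum(w * d) / sum(w)
    dev <- d - mu
    sigma <- 1.4826 * stats::median(abs(dev - stats::median(dev)))
    if (sigma == 0) break
    r <- dev / (tune * sigma)
    wNew <- ((1 - r^2) * (abs(r) < 1))^2
    delta <- max(abs(wNew - w))
    w <- wNew
    if (delta < 1e-10) break
  }
  corrected <- cumsum(c(0, w * (d - mu)))
  corrected <- corrected - mean(corrected) + mean(low)
  corrected + high
}

#' Motion correction by temporal derivative distribution repair (TDDR)
#'
#' Robust-regression motion correction removing both spike artifacts and
#' baseline shifts. Per channel the signal is split at 0.5 Hz (skipped when
#' fs <= 1 Hz); on the low-frequency part the temporal derivative is
#' iteratively reweighted with the Tukey biweight (tuning constant 4.685,
#' robust scale 1.4826 * MAD) until the weights change by less than 1e-10 or
#' 50 iterations; the weighted derivative is integrated, the mean re-added,
#' and the high-frequency part restored.
#'
#' @param rec a \code{NirsRecording} with at least 10 time points.
#' @return the corrected recording.
#' @export
motionCorrectTDDR <- function(rec) {
  stopifnot(is(rec, "NirsRecording"))
  if (nTimepoints(rec) < 10) stop("TDDR needs at least 10 time points")
  fs <- samplingRate(rec)
  for (j in seq_len(ncol(rec@data)))
    rec@data[, j] <- .tddrColumn(rec@data[, j], fs)
  rec <- .refreshHbT(rec)
  appendHistory(rec, "tddr", list(split_hz = if (fs > 1) 0.5 else NA))
}

#' Nuisance regression (short-channel / external series)
#'
#' Regresses each long channel on an intercept plus the supplied nuisance
#' series by ordinary least squares and keeps residual + intercept. The
#' canonical use is removing superficial (scalp) physiology recorded by
#' short-separation reference channels. Collinear regressor columns are
#' dropped with a warning. Per-channel R-squared values are stored in the
#' history record.
#'
#' @param rec a \code{NirsRecording}.
#' @param regressorChannels integer ids of channels whose series (per
#'   chromophore block) serve as regressors; defaults to the channels marked
#'   \code{is_short} in the metadata.
#' @param external optional T x K numeric matrix of external nuisance series
#'   applied to every block (overrides \code{regressorChannels}).
#' @return the cleaned recording (regressor channels pass through unchanged).
#' @export
regressNoise <- function(rec, regressorChannels = NULL, external = NULL) {
  stopifnot(is(rec, "NirsRecording"))
  T <- nTimepoints(rec)
  nch <- nChannels(rec)
  if (is.null(external) && is.null(regressorChannels))
    regressorChannels <- channelInfo(rec)$id[channelInfo(rec)$is_short]
  if (is.null(external) && !length(regressorChannels))
    stop("no regressors: supply regressorChannels or external, or mark short channels")
  if (!is.null(external) && nrow(as.matrix(external)) != T)
    stop("external regressors must have length T = ", T)
  nblk <- max(ncol(rec@data) %/% nch, 1L)
  r2 <- numeric(0)
  warnedCollinear <- FALSE
  for (k in seq_len(nblk)) {
    cols <- (k - 1L) * nch + seq_len(nch)
    R <- if (!is.null(external)) as.matrix(external)
         else rec@data[, (k - 1L) * nch + regressorChannels, drop = FALSE]
    # constant columns carry no signal beyond the intercept; drop silently
    R <- R[, apply(R, 2, stats::sd) > 0, drop = FALSE]
    X <- cbind(1, R)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      if (!warnedCollinear) {
        warning("dropping ", ncol(X) - qrX$rank,
                " collinear regressor column(s)")
        warnedCollinear <- TRUE
      }
      X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
      qrX <- qr(X)
    }
    targets <- if (!is.null(external)) seq_len(nch)
               else setdiff(seq_len(nch), regressorChannels)
    for (i in targets) {
      y <- rec@data[, cols[i]]
      beta <- qr.coef(qrX, y)
      fitted <- X %*% beta
      res <- y - fitted
      rec@data[, cols[i]] <- res + beta[1]
      tss <- sum((y - mean(y))^2)
      r2 <- c(r2, if (tss > 0) 1 - sum(res^2) / tss else NA)
    }
  }
  rec <- .refreshHbT(rec)
  appendHistory(rec, "regress_noise",
                list(regressor_channels = regressorChannels,
                     external_cols = if (is.null(external)) 0
                                     else ncol(as.matrix(external)),
                     r_squared = r2))
}

# rational polyphase resampler: zero-stuff by p, anti-alias/anti-image
# linear-phase FIR (Hamming), compensate the integer group delay, take
# every q-th sample; odd-reflection padding suppresses edge transients
.resamplePoly <- function(x, p, q, Tnew) {
  T <- length(x)
  N <- 10L * max(p, q)                  # half-order at the upsampled rate
  h <- p * as.numeric(signal::fir1(2 * N, 1 / max(p, q), "low"))
  P <- min(max(ceiling(2 * N / p), q) + q, T - 1)   # input-domain padding
  xp <- c(2 * x[1] - x[seq(P + 1, 2)], x, 2 * x[T] - x[seq(T - 1, T - P)])
  xu <- numeric(length(xp) * p)
  xu[seq(1, by = p, length.out = length(xp))] <- xp
  u <- stats::convolve(xu, rev(h), type = "open")   # length + 2N
  # upsampled index of input sample i is (i-1)*p+1; delay N compensated
  idx <- P * p + (seq_len(Tnew) - 1) * q + 1 + N
  idx <- pmin(idx, length(u))
  u[idx]
}

# best small rational approximation p/q of ratio
.ratApprox <- function(r, maxDen = 1000, tol = 1e-9) {
  for (q in seq_len(maxDen)) {
    p <- round(r * q)
    if (p >= 1 && abs(p / q - r) < tol * r) return(c(p, q))
  }
  # fall back to the closest fraction with the largest denominator
  q <- maxDen
  c(max(round(r * q), 1), q)
}

#' Resample a recording to a new sampling rate
#'
#' Polyphase anti-aliased rational resampling of every column. The output
#' length is \code{round(T * newFs / fs)}; attached task timing is unchanged
#' since onsets are stored in seconds.
#'
#' @param rec a \code{NirsRecording}.
#' @param newFs target sampling rate in Hz.
#' @return the resampled recording with updated \code{fs}.
#' @export
resampleRecording <- function(rec, newFs) {
  stopifnot(is(rec, "NirsRecording"), newFs > 0)
  fs <- samplingRate(rec)
  if (newFs / fs > 100) stop("upsampling factor > 100 refused")
  if (abs(newFs - fs) < 1e-12 * fs)
    return(appendHistory(rec, "resample", list(new_fs = newFs)))
  pq <- .ratApprox(newFs / fs)
  T <- nTimepoints(rec)
  Tnew <- round(T * newFs / fs)
  out <- matrix(NA_real_, Tnew, ncol(rec@data))
  for (j in seq_len(ncol(rec@data)))
    out[, j] <- .resamplePoly(rec@data[, j], pq[1], pq[2], Tnew)
  rec@data <- out
  rec@fs <- newFs
  appendHistory(rec, "resample", list(new_fs = newFs, p = pq[1], q = pq[2]))
}

## ---- custom-step registry ----------------------------------------------

.stepRegistry <- new.env(parent = emptyenv())

#' Register a custom preprocessing step
#'
#' Plugs a user-supplied processing method into the pipeline machinery. The
#' callable receives \code{(matrix, fs, params)} — the T x C data matrix of
#' the block the pipeline applies to — and must return a matrix of identical
#' shape (checked at apply time). Registered steps are invocable from a
#' \code{\link{pipelineSpec}} by name and are logged in the history exactly
#' like built-ins.
#'
#' @param name step name (must not collide with a built-in).
#' @param fun function(matrix, fs, params) -> matrix of the same shape.
#' @return \code{name}, invisibly.
#' @export
registerCustomStep <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  builtins <- c("trim", "detrend", "cbsi", "tddr", "filter",
                "regress_noise", "resample")
  if (name %in% builtins) stop("'", name, "' is a built-in step name")
  assign(name, fun, envir = .stepRegistry)
  invisible(name)
}

#' List registered step names (built-ins plus plugins)
#' @return character vector.
#' @export
registeredSteps <- function() {
  c("trim", "detrend", "cbsi", "tddr", "filter", "regress_noise", "resample",
    ls(.stepRegistry))
}

# run one plugin on a recording
.applyCustomStep <- function(rec, name, params) {
  fun <- get(name, envir = .stepRegistry)
  out <- fun(rec@data, samplingRate(rec), params)
  if (!is.matrix(out) || !all(dim(out) == dim(rec@data)))
    stop("custom step '", name, "' changed the data shape (",
         paste(dim(rec@data), collapse = "x"), " -> ",
         paste(dim(out), collapse = "x"), ")")
  rec@data <- out
  rec <- .refreshHbT(rec)
  appendHistory(rec, name, params)
}
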