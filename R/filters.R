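#' @include mbll.R
NULL

#' FilterSpec: a designed digital filter
#'
#' @slot kind "iir_butter", "fir_hamming" or "fft_ideal".
#' @slot mode "low", "high" or "band".
#' @slot cutoffs cutoff frequency/frequencies in Hz.
#' @slot order filter order (ignored for fft_ideal).
#' @slot fs sampling rate the design is valid for, Hz.
#' @slot coef list with components \code{b}, \code{a} (empty for fft_ideal).
#' @slot keepDC logical; for fft_ideal band/high-pass, re-add the signal
#'   mean after filtering.
#' @export
setClass("FilterSpec",
  representation(kind = "character", mode = "character", cutoffs = "numeric",
                 order = "numeric", fs = "numeric", coef = "list",
                 keepDC = "logical"),
  prototype(keepDC = FALSE))

#' Design a digital filter
#'
#' Designs one of the three filter types used for fNIRS band selection:
#' a Butterworth IIR filter (applied zero-phase, forward-backward), a
#' Hamming-window FIR filter (applied single-pass with group-delay
#' compensation of order/2 samples, so the order must be even), or an
#' FFT-based ideal filter that zeroes every frequency bin strictly outside
#' the passband (DC is zeroed for band- and high-pass, kept for low-pass).
#'
#' @param kind "iir_butter" (default order 3), "fir_hamming" (default order
#'   34) or "fft_ideal".
#' @param mode "low", "high" or "band".
#' @param cutoffs cutoff(s) in Hz; length 2 strictly increasing for band.
#' @param fs sampling rate in Hz.
#' @param order filter order; defaults per kind.
#' @param keepDC for fft_ideal band/high-pass: re-add the mean afterwards.
#' @return a \code{FilterSpec}.
#' @examples
#' spec <- designFilter("iir_butter", "band", c(0.01, 0.08), fs = 10)
#' @export
designFilter <- function(kind = c("iir_butter", "fir_hamming", "fft_ideal"),
                         mode = c("band", "low", "high"), cutoffs, fs,
                         order = NULL, keepDC = FALSE) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  nyq <- fs / 2
  if (any(cutoffs <= 0) || any(cutoffs >= nyq))
    stop("cutoffs must lie strictly between 0 and the Nyquist frequency (",
         nyq, " Hz)")
  if (mode == "band") {
    if (length(cutoffs) != 2 || diff(cutoffs) <= 0)
      stop("band mode needs two strictly increasing cutoffs")
  } else if (length(cutoffs) != 1) {
    stop(mode, " mode needs a single cutoff")
  }
  if (is.null(order))
    order <- switch(kind, iir_butter = 3, fir_hamming = 34, fft_ideal = 0)
  coef <- list()
  if (kind == "iir_butter") {
    type <- switch(mode, low = "low", high = "high", band = "pass")
    bt <- signal::butter(order, cutoffs / nyq, type = type)
    coef <- list(b = bt$b, a = bt$a)
  } else if (kind == "fir_hamming") {
    if (order %% 2 != 0)
      stop("FIR order must be even for integer group-delay compensation")
    type <- switch(mode, low = "low", high = "high", band = "pass")
    b <- signal::fir1(order, cutoffs / nyq, type = type,
                      window = signal::hamming(order + 1))
    coef <- list(b = as.numeric(b), a = 1)
  }
  new("FilterSpec", kind = kind, mode = mode, cutoffs = cutoffs,
      order = order, fs = fs, coef = coef, keepDC = keepDC)
}

# steady-state initial conditions of a direct-form II transposed IIR so
# that a constant input produces a constant output from sample one
.lfilterZi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  A <- diag(n - 1)
  A[, 1] <- A[, 1] + a[-1]
  if (n > 2) for (i in seq_len(n - 2)) A[i, i + 1] <- A[i, i + 1] - 1
  solve(A, b[-1] - a[-1] * b[1])
}

# one-pass IIR (direct-form II transposed) over all columns at once;
# Zinit is the (n-1) x C initial state
.lfilterMat <- function(b, a, X, Zinit) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  T <- nrow(X); C <- ncol(X)
  z <- Zinit
  Y <- matrix(0, T, C)
  for (t in seq_len(T)) {
    xt <- X[t, ]
    yt <- b[1] * xt + z[1, ]
    if (n > 2)
      z[seq_len(n - 2), ] <- outer(b[2:(n - 1)], xt) +
        z[2:(n - 1), , drop = FALSE] - outer(a[2:(n - 1)], yt)
    z[n - 1, ] <- b[n] * xt - a[n] * yt
    Y[t, ] <- yt
  }
  Y
}

# zero-phase IIR (forward-backward) with odd-reflection padding and
# steady-state initial conditions, eliminating start-up transients
.filtfiltPadMat <- function(b, a, X) {
  X <- as.matrix(X)
  T <- nrow(X)
  nfact <- min(3 * (max(length(a), length(b)) - 1), T - 1)
  zi <- .lfilterZi(b, a)
  pre <- 2 * matrix(X[1, ], nfact, ncol(X), byrow = TRUE) -
    X[seq(nfact + 1, 2), , drop = FALSE]
  post <- 2 * matrix(X[T, ], nfact, ncol(X), byrow = TRUE) -
    X[seq(T - 1, T - nfact), , drop = FALSE]
  Xp <- rbind(pre, X, post)
  Y <- .lfilterMat(b, a, Xp, outer(zi, Xp[1, ]))
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y <- .lfilterMat(b, a, Y, outer(zi, Y[1, ]))
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y[(nfact + 1):(nfact + T), , drop = FALSE]
}

.filtfiltPad <- function(b, a, x) .filtfiltPadMat(b, a, matrix(x))[, 1]

# ideal FFT filter of one column
.fftIdeal <- function(x, spec) {
  N <- length(x)
  X <- stats::fft(x)
  k <- 0:(N - 1)
  f <- pmin(k, N - k) * spec@fs / N
  keep <- switch(spec@mode,
    low  = f <= spec@cutoffs[1],
    high = f >= spec@cutoffs[1] & k != 0,
    band = f >= spec@cutoffs[1] & f <= spec@cutoffs[2] & k != 0)
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / N
  if (spec@keepDC && spec@mode != "low") y <- y + mean(x)
  y
}

#' Apply a designed filter to a matrix or recording
#'
#' IIR filters run forward-backward (zero phase; effective magnitude
#' response |H|^2). FIR filters run single-pass with the order/2-sample
#' group delay removed. The FFT-ideal filter operates on the full-length
#' spectrum of each column.
#'
#' @param x numeric matrix (time in rows) or \code{NirsRecording}.
#' @param spec a \code{FilterSpec} designed at the same sampling rate.
#' @param ... unused.
#' @return object of the same type as \code{x}.
#' @export
applyFilter <- function(x, spec, ...) {
  if (is(x, "NirsRecording")) {
    if (abs(samplingRate(x) - spec@fs) > 1e-9 * spec@fs)
      stop("filter was designed for fs = ", spec@fs, " Hz, recording has ",
           samplingRate(x))
    x@data <- applyFilter(recData(x), spec)
    x <- .refreshHbT(x)
    return(appendHistory(x, "filter",
                         list(kind = spec@kind, mode = spec@mode,
                              cutoffs = spec@cutoffs, order = spec@order)))
  }
  m <- as.matrix(x)
  if (spec@kind == "iir_butter")
    return(.filtfiltPadMat(spec@coef$b, spec@coef$a, m))
  out <- m
  for (j in seq_len(ncol(m))) {
    xj <- m[, j]
    out[, j] <- switch(spec@kind,
      fir_hamming = {
        d <- spec@order / 2
        y <- as.numeric(signal::filter(spec@coef$b, 1, c(xj, numeric(d))))
        y[(d + 1):(d + length(xj))]
      },
      fft_ideal = .fftIdeal(xj, spec))
  }
  out
}

#' Single-pass transfer function of a designed filter
#'
#' Evaluates the frequency response \eqn{H(f)} of the designed coefficients
#' (one forward pass; the zero-phase IIR application realises |H(f)|^2).
#'
#' @param spec a \code{FilterSpec} with coefficients (not fft_ideal).
#' @param f frequencies in Hz.
#' @return complex vector of responses.
#' @export
filterResponse <- function(spec, f) {
  if (spec@kind == "fft_ideal")
    stop("fft_ideal has no rational transfer function; its response is the bin mask")
  w <- 2 * pi * f / spec@fs
  b <- spec@coef$b
  a <- spec@coef$a
  num <- vapply(w, function(wi) sum(b * exp(-1i * wi * (seq_along(b) - 1))),
                complex(1))
  den <- vapply(w, function(wi) sum(a * exp(-1i * wi * (seq_along(a) - 1))),
                complex(1))
  num / den
}
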