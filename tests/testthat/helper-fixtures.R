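# shared fixtures: everything built in code, no stored data

# T samples of A*cos(2*pi*f*t + phase) at fs; with T*f/fs integer the
# frequency sits exactly on a Fourier bin
onBinSinusoid <- function(f, A = 1, fs = 10, T = 2000, phase = 0) {
  t <- (seq_len(T) - 1) / fs
  A * cos(2 * pi * f * t + phase)
}

hbRecording <- function(hbo, hbr, fs = 10) {
  NirsRecording(cbind(as.matrix(hbo), as.matrix(hbr)), fs = fs, kind = "hb",
                chromophores = c("HbO", "HbR"))
}

# brute-force pairwise Pearson from the definition
bruteCor <- function(m) {
  C <- ncol(m)
  out <- matrix(NA_real_, C, C)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    xi <- m[, i] - mean(m[, i]); xj <- m[, j] - mean(m[, j])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}

# brute-force BH / Bonferroni flag sets from their definitions
bruteBH <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  if (!length(k)) return(rep(FALSE, m))
  p <= ps[max(k)]
}
bruteBonferroni <- function(p, q) p <= q / length(p)
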