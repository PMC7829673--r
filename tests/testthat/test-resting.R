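test_that("amplitude spectrum recovers on-bin cosine components exactly", {
  sp0 <- amplitudeSpectrum(rep(5, 100), fs = 10)
  expect_equal(sp0@a0, 5)
  expect_lt(max(sp0@Ak), 1e-12)
  x <- onBinSinusoid(0.05, A = 3, fs = 10, T = 2000, phase = -0.7)
  sp <- amplitudeSpectrum(x, fs = 10)
  k <- which.min(abs(sp@fk - 0.05))
  expect_equal(sp@fk[k], 0.05)
  expect_equal(sp@Ak[k], 3, tolerance = 1e-9)
  expect_lt(max(sp@Ak[-k]), 1e-9)
  # phase convention: x = a0 + A cos(2 pi f t - phi)
  expect_equal(sp@phik[k], 0.7, tolerance = 1e-9)
  expect_error(amplitudeSpectrum(1:3, 10), "at least 4")
})

test_that("spectrum satisfies Parseval for white noise (odd and even N)", {
  set.seed(12)
  for (N in c(512, 511)) {
    x <- rnorm(N)
    sp <- amplitudeSpectrum(x, fs = 7)
    expect_equal(spectrumMeanSquare(sp), mean(x^2), tolerance = 1e-6)
  }
})

test_that("ALFF equals the in-band bin average; fALFF is its spectral fraction", {
  T <- 2000; fs <- 10
  x <- onBinSinusoid(0.05, A = 2, fs = fs, T = T)
  m <- cbind(x, 3 * x)
  attr(m, "fs") <- fs
  res <- computeALFF(m)
  tab <- alffTable(res)
  # band 0.01..0.08 at df = fs/T = 0.005: bins 0.01,0.015,...,0.08 -> 15
  expect_identical(res@Nk, 15L)
  expect_equal(tab$alff[1], 2 / 15, tolerance = 1e-9)
  expect_equal(tab$falff[1], 1, tolerance = 1e-9)
  # two channels with ALFF a and 3a give population z-scores -1, +1
  expect_equal(tab$zalff, c(-1, 1), tolerance = 1e-9)
  # ALFF is invariant to constants and linear in amplitude
  m2 <- cbind(x + 10, 3 * x); attr(m2, "fs") <- fs
  expect_equal(alffTable(computeALFF(m2))$alff, tab$alff, tolerance = 1e-12)
  expect_equal(tab$alff[2], 3 * tab$alff[1], tolerance = 1e-12)
  # identical channels make z-standardisation undefined
  m3 <- cbind(x, x); attr(m3, "fs") <- fs
  expect_error(computeALFF(m3), "sd = 0")
})

test_that("fALFF lies in [0,1] on arbitrary signals", {
  set.seed(13)
  m <- matrix(rnorm(500 * 6), 500, 6) +
    outer(onBinSinusoid(0.03, T = 500), runif(6))
  attr(m, "fs") <- 10
  tab <- alffTable(computeALFF(m))
  expect_true(all(tab$falff >= 0 & tab$falff <= 1))
  expect_equal(mean(tab$zalff), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(tab$zalff^2)), 1, tolerance = 1e-9)
  expect_equal(sqrt(mean(tab$zfalff^2)), 1, tolerance = 1e-9)
})

test_that("FC matrix equals brute-force Pearson on small instances", {
  set.seed(14)
  for (C in c(3, 7, 10)) {
    m <- matrix(rnorm(50 * C), 50, C)
    cm <- fcMatrix(m)
    expect_equal(fcValues(cm), bruteCor(m), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(diag(fcValues(cm)), rep(1, C), ignore_attr = TRUE)
  }
  # hand-checkable cases
  x <- rnorm(50)
  expect_equal(fcValues(fcMatrix(cbind(x, -x)))[1, 2], -1)
  expect_warning(cmz <- fcMatrix(cbind(x, rep(1, 50), x + rnorm(50))),
                 "zero-variance")
  expect_true(all(is.na(fcValues(cmz)[2, ])))
})

test_that("ROI modes average member series before correlating", {
  set.seed(15)
  m <- matrix(rnorm(200 * 5), 200, 5)
  rois <- list(a = c(1L, 2L), b = c(3L, 4L, 5L))
  cm <- fcMatrix(m, mode = "roi2roi", roiSets = rois)
  manual <- cor(rowMeans(m[, 1:2]), rowMeans(m[, 3:5]))
  expect_equal(fcValues(cm)[1, 2], manual, tolerance = 1e-12)
  seed <- fcMatrix(m, mode = "roi2whole", roiSets = rois["a"])
  expect_identical(dim(fcValues(seed)), c(1L, 5L))
  expect_equal(fcValues(seed)[1, 3], cor(rowMeans(m[, 1:2]), m[, 3]),
               tolerance = 1e-12)
  expect_error(fcMatrix(m, mode = "roi2roi", roiSets = list()), "roiSets")
})

test_that("Fisher z output is arctanh(r)", {
  set.seed(16)
  m <- matrix(rnorm(300), 100, 3)
  r <- fcValues(fcMatrix(m))
  z <- fcValues(fcMatrix(m, fisherZ = TRUE))
  expect_equal(z[1, 2], atanh(r[1, 2]), tolerance = 1e-12)
})

test_that("sparsity thresholding keeps the largest edges with tie handling", {
  v <- matrix(0, 4, 4)
  v[upper.tri(v)] <- c(0.1, 0.5, 0.3, 0.9, 0.7, 0.2)
  v <- v + t(v); diag(v) <- 1
  cm <- new("ConnectivityMatrix", values = v, mode = "wholebrain",
            channelIds = 1:4, fisherZ = FALSE,
            thresholdState = list(method = "none"))
  th <- thresholdMatrix(cm, "sparsity", 0.5)
  kept <- fcValues(th)[upper.tri(v)]
  expect_identical(sum(kept > 0), 3L)
  expect_setequal(kept[kept > 0], c(0.9, 0.7, 0.5))
  expect_equal(thresholdState(th)$attained, 0.5)
  # s = 1 keeps everything
  full <- thresholdMatrix(cm, "sparsity", 1)
  expect_equal(fcValues(full), v)
  # ties at the cutoff are all kept and attained sparsity reported
  vt <- matrix(0, 4, 4); vt[upper.tri(vt)] <- c(0.5, 0.5, 0.5, 0.9, 0.1, 0.1)
  vt <- vt + t(vt); diag(vt) <- 1
  cmt <- new("ConnectivityMatrix", values = vt, mode = "wholebrain",
             channelIds = 1:4, fisherZ = FALSE,
             thresholdState = list(method = "none"))
  tht <- thresholdMatrix(cmt, "sparsity", 1/3)
  expect_identical(sum(fcValues(tht)[upper.tri(vt)] > 0), 4L)
  expect_equal(thresholdState(tht)$attained, 4/6)
  expect_error(thresholdMatrix(tht, "sparsity", 0.5), "already")
  expect_error(thresholdMatrix(cmt, "sparsity", 1.5), "sparsity")
})

test_that("absolute thresholding zeroes sub-threshold edges", {
  v <- matrix(c(1, .6, .2, .6, 1, -.4, .2, -.4, 1), 3, 3)
  cm <- new("ConnectivityMatrix", values = v, mode = "wholebrain",
            channelIds = 1:3, fisherZ = FALSE,
            thresholdState = list(method = "none"))
  th <- thresholdMatrix(cm, "absolute", 0.5)
  expect_equal(fcValues(th)[1, 2], 0.6)
  expect_equal(fcValues(th)[1, 3], 0)
  expect_equal(fcValues(th)[2, 3], 0)
  expect_equal(diag(fcValues(th)), rep(1, 3), ignore_attr = TRUE)
  empty <- thresholdMatrix(cm, "absolute", 0.99)
  expect_equal(sum(fcValues(empty)[upper.tri(v)] != 0), 0)
})
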