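test_that("trimming drops the requested periods and shifts task onsets", {
  rec <- hbRecording(matrix(rnorm(100), 100, 1), matrix(rnorm(100), 100, 1),
                     fs = 10)
  expect_identical(nTimepoints(trimRecording(rec, 0, 0)), 100L)
  expect_identical(nTimepoints(trimRecording(rec, 2, 0)), 80L)
  expect_identical(nTimepoints(trimRecording(rec, 1.5, 2.5)), 60L)
  expect_error(trimRecording(rec, 6, 5), "leaves nothing")
  d <- TaskDesign(data.frame(condition = "a", onset_s = c(1, 6),
                             duration_s = 1))
  expect_warning(out <- trimRecording(rec, 2, 0, design = d), "dropped")
  expect_equal(out$design@conditions$onset_s, 4)
})

test_that("polynomial detrending removes polynomials exactly", {
  t <- (0:99) / 10
  lin <- 3 + 0.5 * t
  rec <- hbRecording(matrix(lin), matrix(2 - 0.1 * t), fs = 10)
  out <- detrendRecording(rec, order = 1)
  expect_lt(max(abs(recData(out))), 1e-9)
  # order 0 is exact mean removal
  x <- rnorm(100)
  rec0 <- hbRecording(matrix(x), matrix(x), fs = 10)
  expect_equal(chromData(detrendRecording(rec0, 0), "HbO")[, 1],
               x - mean(x), ignore_attr = TRUE)
  # output means are zero at any order; slow sinusoids survive a linear fit
  s <- onBinSinusoid(0.05, T = 1000)
  recS <- hbRecording(matrix(s), matrix(-s), fs = 10)
  outS <- detrendRecording(recS, 1)
  expect_lt(abs(mean(chromData(outS, "HbO"))), 1e-9)
  expect_gt(cor(chromData(outS, "HbO")[, 1], s), 0.999)
  expect_error(detrendRecording(rec, order = 200), "time points")
})

test_that("CBSI enforces exact anticorrelation and kills common-mode artifacts", {
  set.seed(21)
  # already perfectly anticorrelated input is left unchanged
  hbo <- onBinSinusoid(0.05, T = 500) + rnorm(500, sd = 0.01)
  alpha <- 2
  rec <- hbRecording(matrix(hbo), matrix(-hbo / alpha), fs = 10)
  out <- motionCorrectCBSI(rec)
  expect_equal(chromData(out, "HbO")[, 1], hbo, tolerance = 1e-9,
               ignore_attr = TRUE)
  # pure common-mode artifact (HbO = HbR) is annihilated
  art <- rnorm(500)
  recA <- hbRecording(matrix(art), matrix(art), fs = 10)
  outA <- motionCorrectCBSI(recA)
  expect_lt(max(abs(recData(outA))), 1e-12)
  # arbitrary input: output correlation is exactly -1
  recR <- hbRecording(matrix(rnorm(500)), matrix(rnorm(500)), fs = 10)
  outR <- motionCorrectCBSI(recR)
  expect_equal(cor(chromData(outR, "HbO")[, 1], chromData(outR, "HbR")[, 1]),
               -1)
  # zero-variance HbR channel is skipped with a warning
  recZ <- hbRecording(matrix(rnorm(500)), matrix(0, 500, 1), fs = 10)
  expect_warning(outZ <- motionCorrectCBSI(recZ), "zero HbR variance")
  expect_equal(chromData(outZ, "HbO"), chromData(recZ, "HbO"))
})

test_that("TDDR repairs steps and spikes but passes clean signals", {
  # constant signal is returned unchanged (zero derivative)
  recC <- hbRecording(matrix(5, 200, 1), matrix(2, 200, 1), fs = 10)
  expect_equal(recData(motionCorrectTDDR(recC)), recData(recC),
               tolerance = 1e-9)
  # clean slow signal passes nearly untouched
  s <- onBinSinusoid(0.05, T = 1200)
  recS <- hbRecording(matrix(s), matrix(-s / 3), fs = 10)
  outS <- motionCorrectTDDR(recS)
  expect_gt(cor(chromData(outS, "HbO")[, 1], s), 0.99)
  # injected step of ~10x the signal sd: demeaned RMSE to clean drops
  set.seed(31)
  clean <- s + rnorm(1200, sd = 0.05)
  x <- clean + 7 * (seq_along(s) > 600)
  recM <- hbRecording(matrix(x), matrix(-x / 3), fs = 10)
  outM <- motionCorrectTDDR(recM)
  dm <- function(v) v - mean(v)
  before <- sqrt(mean((dm(x) - dm(clean))^2))
  after <- sqrt(mean((dm(chromData(outM, "HbO")[, 1]) - dm(clean))^2))
  expect_lt(after, before)
  expect_lt(after, before / 3)
  expect_error(motionCorrectTDDR(hbRecording(matrix(1:5), matrix(1:5))),
               "at least 10")
})

test_that("FFT-ideal filter is exact on on-bin sinusoids", {
  fs <- 10; T <- 1000
  spec <- designFilter("fft_ideal", "band", c(0.01, 0.08), fs = fs)
  outOfBand <- onBinSinusoid(0.2, T = T)
  expect_lt(max(abs(applyFilter(matrix(outOfBand), spec))), 1e-9)
  inBand <- onBinSinusoid(0.05, T = T)
  expect_equal(applyFilter(matrix(inBand), spec)[, 1], inBand,
               tolerance = 1e-9, ignore_attr = TRUE)
  # DC is zeroed for band-pass, kept for low-pass
  expect_lt(max(abs(applyFilter(matrix(inBand + 4), spec) -
                    applyFilter(matrix(inBand), spec))), 1e-9)
  lp <- designFilter("fft_ideal", "low", 0.5, fs = fs)
  expect_equal(applyFilter(matrix(inBand + 4), lp)[, 1], inBand + 4,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Butterworth and Hamming designs match textbook responses", {
  bw <- designFilter("iir_butter", "low", 0.1, fs = 10, order = 3)
  expect_equal(abs(filterResponse(bw, 0.1)), 1 / sqrt(2), tolerance = 1e-6)
  # analog-prototype magnitude |H|=1/sqrt(1+(f/fc)^(2n)) holds near cutoff
  expect_equal(abs(filterResponse(bw, 0.05)),
               1 / sqrt(1 + (0.05 / 0.1)^6), tolerance = 1e-2)
  fir <- designFilter("fir_hamming", "low", 0.5, fs = 10)
  expect_identical(fir@order, 34)
  expect_length(fir@coef$b, 35L)
  # linear phase: symmetric taps
  expect_lt(max(abs(fir@coef$b - rev(fir@coef$b))), 1e-12)
  # group-delay compensation aligns the output with the input
  x <- onBinSinusoid(0.05, T = 600)
  y <- applyFilter(matrix(x), fir)[, 1]
  expect_gt(cor(x[100:500], y[100:500]), 0.9999)
  expect_error(designFilter("iir_butter", "low", 6, fs = 10), "Nyquist")
  expect_error(designFilter("iir_butter", "band", c(0.08, 0.01), fs = 10),
               "increasing")
})

test_that("zero-phase IIR application doubles the attenuation in dB", {
  spec <- designFilter("iir_butter", "low", 0.1, fs = 10, order = 3)
  x <- onBinSinusoid(0.4, T = 4000)
  y <- applyFilter(matrix(x), spec)[, 1]
  onePass <- abs(filterResponse(spec, 0.4))
  gain <- sqrt(mean(y[500:3500]^2) / mean(x[500:3500]^2))
  expect_equal(gain, onePass^2, tolerance = 0.05)
})

test_that("noise regression removes shared regressors by OLS", {
  set.seed(41)
  short <- as.numeric(arima.sim(list(ar = 0.9), 500))
  slow <- onBinSinusoid(0.02, T = 500)
  long <- 2 * short + slow
  hbo <- cbind(long, short)
  rec <- NirsRecording(cbind(hbo, -hbo / 3), fs = 10, kind = "hb",
                       channels = data.frame(id = 1:2, source_idx = 1:2,
                                             detector_idx = 1:2,
                                             is_short = c(FALSE, TRUE)))
  out <- regressNoise(rec)
  resid <- chromData(out, "HbO")[, 1]
  expect_lt(abs(cor(resid, short)), 1e-8)
  h <- processingHistory(out)
  expect_true(all(h[[length(h)]]$params$r_squared <= 1))
  # zero regressor leaves the data unchanged (intercept only)
  recZ <- hbRecording(matrix(rnorm(100)), matrix(rnorm(100)))
  outZ <- regressNoise(recZ, external = matrix(0, 100, 1))
  expect_equal(recData(outZ), recData(recZ), tolerance = 1e-9)
  # duplicated regressors collapse to one with a warning
  expect_warning(outD <- regressNoise(recZ, external = cbind(short[1:100],
                                                             short[1:100])),
                 "collinear")
  outS <- regressNoise(recZ, external = matrix(short[1:100]))
  expect_equal(recData(outD), recData(outS), tolerance = 1e-9)
})

test_that("resampling matches the analytic decimation of a slow sinusoid", {
  s <- onBinSinusoid(0.05, fs = 10, T = 1000)
  rec <- hbRecording(matrix(s), matrix(-s), fs = 10)
  same <- resampleRecording(rec, 10)
  expect_identical(nTimepoints(same), 1000L)
  down <- resampleRecording(rec, 5)
  expect_identical(nTimepoints(down), 500L)
  expect_equal(samplingRate(down), 5)
  analytic <- onBinSinusoid(0.05, fs = 5, T = 500)
  expect_gt(cor(chromData(down, "HbO")[, 1], analytic), 0.999)
  rec2 <- hbRecording(matrix(s[1:100]), matrix(s[1:100]), fs = 10)
  expect_identical(nTimepoints(resampleRecording(rec2, 4)), 40L)
  expect_error(resampleRecording(rec, 2000), "factor")
})

test_that("custom steps plug into the registry and pipeline", {
  rec <- hbRecording(matrix(rnorm(100)), matrix(rnorm(100)))
  registerCustomStep("identity_step", function(m, fs, p) m)
  registerCustomStep("scale_step", function(m, fs, p) m * p$factor)
  expect_true(all(c("identity_step", "scale_step") %in% registeredSteps()))
  out <- applyPipeline(rec, pipelineSpec(list(
    list(name = "identity_step", params = list()),
    list(name = "scale_step", params = list(factor = 2)))))
  expect_equal(recData(out), 2 * recData(rec))
  expect_equal(vapply(processingHistory(out), `[[`, "", "name"),
               c("identity_step", "scale_step"))
  registerCustomStep("bad_step", function(m, fs, p) m[-1, , drop = FALSE])
  expect_error(applyPipeline(rec, pipelineSpec("bad_step")), "shape")
  expect_error(registerCustomStep("detrend", identity), "built-in")
})

test_that("serialized pipelines re-run to bitwise-identical output", {
  s <- generateScenario(scenarioSpec(nChannels = 2, durationS = 30,
                                     noiseSd = 0.2, seed = 6))
  ps <- defaultRestingPipeline()
  f <- withr::local_tempfile(fileext = ".yml")
  writePipelineSpec(ps, f)
  ps2 <- readPipelineSpec(f)
  out1 <- applyPipeline(s$recording, ps)
  out2 <- applyPipeline(s$recording, ps2)
  expect_identical(recData(out1), recData(out2))
  expect_identical(length(processingHistory(out1)),
                   length(processingHistory(s$recording)) + length(ps@steps))
})
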