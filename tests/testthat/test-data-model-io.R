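test_that("NirsRecording validity enforces its invariants", {
  expect_s4_class(NirsRecording(matrix(rnorm(40), 10, 4), fs = 10), "NirsRecording")
  expect_error(NirsRecording(matrix(rnorm(4), 1, 4), fs = 10), "2 time points")
  expect_error(NirsRecording(matrix(rnorm(40), 10, 4), fs = -1), "positive")
  expect_error(NirsRecording(matrix(rnorm(50), 10, 5), fs = 10),
               "not divisible")
  # HbT must equal HbO + HbR
  hbo <- matrix(rnorm(20), 10, 2); hbr <- matrix(rnorm(20), 10, 2)
  good <- NirsRecording(cbind(hbo, hbr, hbo + hbr), fs = 10,
                        chromophores = c("HbO", "HbR", "HbT"))
  expect_s4_class(good, "NirsRecording")
  expect_error(NirsRecording(cbind(hbo, hbr, hbo + hbr + 1), fs = 10,
                             chromophores = c("HbO", "HbR", "HbT")),
               "HbT")
})

test_that("every mutating operation appends exactly one history record", {
  rec <- hbRecording(matrix(rnorm(200), 100, 2), matrix(rnorm(200), 100, 2))
  n0 <- length(processingHistory(rec))
  rec <- detrendRecording(rec)
  expect_length(processingHistory(rec), n0 + 1)
  rec <- motionCorrectCBSI(rec)
  expect_length(processingHistory(rec), n0 + 2)
  rec <- trimRecording(rec, 1, 0)
  expect_length(processingHistory(rec), n0 + 3)
  expect_equal(vapply(processingHistory(rec), `[[`, "", "name"),
               c("detrend", "cbsi", "trim"))
})

test_that("SNIRF round-trip is lossless for data and metadata", {
  s <- generateScenario(scenarioSpec(nChannels = 3, durationS = 15,
                                     noiseSd = 0.2, seed = 11))
  f <- withr::local_tempfile(fileext = ".snirf")
  writeSnirf(s$recording, f)
  back <- readSnirf(f)
  expect_identical(recData(back), unname(recData(s$recording)))
  expect_equal(samplingRate(back), 10)
  expect_identical(signalKind(back), "hb")
  expect_identical(chromophores(back), c("HbO", "HbR"))
  expect_identical(channelInfo(back)$source_idx,
                   channelInfo(s$recording)$source_idx)
})

test_that("intensity SNIRF with 2 wavelengths x 4 channels yields 8 columns", {
  I <- matrix(abs(rnorm(80, 100, 5)), 10, 8)
  rec <- NirsRecording(I, fs = 5, kind = "intensity",
                       wavelengths = c(760, 850))
  f <- withr::local_tempfile(fileext = ".snirf")
  writeSnirf(rec, f)
  back <- readSnirf(f)
  expect_identical(signalKind(back), "intensity")
  expect_identical(ncol(recData(back)), 8L)
  expect_identical(nChannels(back), 4L)
  expect_equal(back@wavelengths, c(760, 850))
})

test_that("missing required SNIRF group is reported by name", {
  f <- withr::local_tempfile(fileext = ".snirf")
  rhdf5::h5createFile(f)
  rhdf5::h5createGroup(f, "nirs")
  rhdf5::h5write("1.0", f, "formatVersion")
  rhdf5::h5closeAll()
  expect_error(readSnirf(f), "/nirs/data1")
  f2 <- withr::local_tempfile(fileext = ".snirf")
  rhdf5::h5createFile(f2)
  rhdf5::h5write("1.0", f2, "formatVersion")
  rhdf5::h5closeAll()
  expect_error(readSnirf(f2), "/nirs")
})

test_that("nonuniform SNIRF time vectors are rejected, not resampled", {
  s <- generateScenario(scenarioSpec(nChannels = 2, durationS = 5, seed = 3))
  f <- withr::local_tempfile(fileext = ".snirf")
  writeSnirf(s$recording, f)
  tv <- seq(0, by = 0.1, length.out = nTimepoints(s$recording))
  tv[10] <- tv[10] + 0.02
  rhdf5::h5delete(f, "nirs/data1/time")
  rhdf5::h5write(tv, f, "nirs/data1/time")
  rhdf5::h5closeAll()
  expect_error(readSnirf(f), "nonuniform")
})

test_that("manual CSV dialect round-trips and accounts for NaN cells", {
  s <- generateScenario(scenarioSpec(nChannels = 2, durationS = 10,
                                     noiseSd = 0.3, seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  writeManualCsv(s$recording, f)
  back <- readManualCsv(f, fs = 10)
  expect_equal(recData(back), unname(recData(s$recording)), tolerance = 1e-12)
  expect_identical(nTimepoints(back), 100L)
  expect_identical(nChannels(back), 2L)
  # inject NaN cells and count them through the QC path
  lines <- readLines(f)
  fields <- strsplit(lines[5], ",")[[1]]
  fields[2] <- "NaN"
  lines[5] <- paste(fields, collapse = ",")
  writeLines(lines, f)
  withNa <- readManualCsv(f, fs = 10)
  h <- processingHistory(withNa)
  expect_identical(h[[length(h)]]$params$n_missing, 1L)
  qc <- qcSummary(withNa)
  expect_equal(sum(qc@channelTable$missing_frac) * 100, 1)
})

test_that("malformed manual CSV input is rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3", "4,5"), f)
  expect_error(readManualCsv(f, fs = 10), "ragged")
  writeLines(c("a,b,c,d,e", paste(1:5, collapse = ","),
               paste(6:10, collapse = ",")), f)
  expect_error(readManualCsv(f, fs = 10), "not divisible")
  writeLines(c("a,b", "1,x", "2,3"), f)
  expect_error(readManualCsv(f, fs = 10), "non-numeric")
})

test_that("standard 3x5 probe has 22 channels and round-trips as JSON", {
  p <- standardProbe("3x5")
  expect_identical(nrow(p@pairs), 22L)
  expect_identical(nrow(p@sources) + nrow(p@detectors), 15L)
  f <- withr::local_tempfile(fileext = ".json")
  writeProbeSetup(p, f)
  back <- readProbeSetup(f)
  expect_equal(back@pairs, p@pairs, ignore_attr = TRUE)
  expect_equal(back@sources$x, p@sources$x)
  # invalid pair references are caught
  expect_error(ProbeSetup(p@sources, p@detectors, rbind(p@pairs, c(99, 1))),
               "nonexistent source")
})

test_that("task design TSV round-trips and validity holds", {
  d <- TaskDesign(data.frame(condition = c("a", "a", "b"),
                             onset_s = c(5, 45, 20), duration_s = c(10, 10, 0)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTaskDesign(d, f)
  back <- readTaskDesign(f)
  expect_equal(back@conditions, d@conditions, ignore_attr = TRUE)
  expect_error(TaskDesign(data.frame(condition = "a", onset_s = -1,
                                     duration_s = 1)), "nonnegative")
  expect_error(TaskDesign(data.frame(condition = c("a", "a"),
                                     onset_s = c(10, 5),
                                     duration_s = c(1, 1))),
               "strictly increasing")
})

test_that("node/edge export writes viewer-conformant text and round-trips", {
  m <- matrix(rnorm(200), 50, 4)
  cm <- fcMatrix(m)
  coords <- cbind(1:4, 5:8, 9:12)
  prefix <- file.path(withr::local_tempdir(), "net")
  files <- exportNodeEdge(cm, coords, prefix)
  node <- read.table(paste0(prefix, ".node"))
  expect_identical(dim(node), c(4L, 6L))
  expect_equal(as.matrix(node[, 1:3]), coords, ignore_attr = TRUE)
  edge <- readNetworkMatrix(paste0(prefix, ".edge"))
  expect_equal(edge, fcValues(cm), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(exportNodeEdge(cm, coords[1:3, ], prefix), "does not match")
  # identity matrix exports as identity text
  eye <- new("ConnectivityMatrix", values = diag(3), mode = "wholebrain",
             channelIds = 1:3, fisherZ = FALSE,
             thresholdState = list(method = "none"))
  f <- withr::local_tempfile()
  exportNetwork(eye, f)
  expect_equal(readNetworkMatrix(f), diag(3), ignore_attr = TRUE)
  expect_error(exportNetwork(matrix(1:4, 2, 2), f), "symmetric")
})
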