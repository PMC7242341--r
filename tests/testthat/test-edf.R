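test_that("EDF round-trip preserves structure and signal within 16-bit quantization", {
  rec <- noiseRecording(fs = 256, durationS = 10, seed = 3)
  rec@data <- rec@data * 40          # ~40 uV scale
  f <- tempfile(fileext = ".edf")
  writeEDF(rec, f)
  back <- readEDFRecording(f, "s1", "case")
  expect_identical(channelLabels(back), channelLabels(rec))
  expect_identical(samplingRate(back), 256)
  expect_identical(dim(signalData(back)), dim(signalData(rec)))
  relRMS <- sqrt(mean((signalData(back) - signalData(rec))^2)) /
    sqrt(mean(signalData(rec)^2))
  expect_lt(relRMS, 1e-3)
})

test_that("raw clinical labels come back normalized", {
  rec <- EEGRecording("s2", "contrast", 128, c("T7", "P7", "Cz"),
                      matrix(rnorm(3 * 256), 3), normalize = FALSE)
  f <- tempfile(fileext = ".edf")
  writeEDF(rec, f, rawLabels = c("EEG T3-REF", "EEG T5-REF", "cz"))
  back <- readEDFRecording(f, "s2", "contrast")
  expect_identical(channelLabels(back), c("T7", "P7", "Cz"))
})

test_that("mixed per-channel sampling rates are rejected, not resampled", {
  rec <- EEGRecording("s3", "case", 256, c("C3", "C4"),
                      matrix(rnorm(2 * 512), 2), normalize = FALSE)
  f <- tempfile(fileext = ".edf")
  writeEDF(rec, f, samplesPerRecord = c(256, 128))
  expect_error(readEDFRecording(f, "s3", "case"), "differing sampling rates")
})

test_that("annotation channels are dropped and missing files error by name", {
  rec <- EEGRecording("s4", "case", 128, c("C3", "EDF Annotations"),
                      matrix(rnorm(2 * 256), 2), normalize = FALSE)
  f <- tempfile(fileext = ".edf")
  writeEDF(rec, f)
  back <- readEDFRecording(f, "s4", "case")
  expect_identical(channelLabels(back), "C3")
  expect_identical(nChannels(back), 1L)

  missing <- file.path(tempdir(), "no-such-file.edf")
  expect_error(readEDFRecording(missing, "x", "case"), "no-such-file")
  bad <- tempfile(fileext = ".edf")
  writeLines("not an edf", bad)
  expect_error(readEDFRecording(bad, "x", "case"))
})

test_that("an external EDF reader (python-mne) agrees with the writer", {
  py <- Sys.which("python")
  rec <- noiseRecording(fs = 128, durationS = 4, seed = 9)
  rec@data <- rec@data * 30
  f <- tempfile(fileext = ".edf")
  writeEDF(rec, f)
  out <- tempfile(fileext = ".csv")
  code <- paste0(
    "import mne, numpy as np, sys\n",
    "raw = mne.io.read_raw_edf(sys.argv[1], preload=True, verbose='ERROR')\n",
    "np.savetxt(sys.argv[2], raw.get_data() * 1e6, delimiter=',')\n")
  status <- system2(py, c("-c", shQuote(code), shQuote(f), shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  ext <- as.matrix(utils::read.csv(out, header = FALSE))
  expect_identical(dim(ext), dim(signalData(rec)))
  relRMS <- sqrt(mean((ext - signalData(rec))^2)) /
    sqrt(mean(signalData(rec)^2))
  expect_lt(relRMS, 1e-3)
})

test_that("cohort manifests round-trip and validate group labels", {
  m <- data.frame(subject_id = c("a", "b"), group = c("case", "contrast"),
                  edf_path = c("a.edf", "b.edf"))
  f <- tempfile(fileext = ".csv")
  writeCohortManifest(m, f)
  expect_identical(readCohortManifest(f), m)
  bad <- m; bad$group[1] <- "patient"
  writeCohortManifest(bad, f)
  expect_error(readCohortManifest(f), "patient")
})
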