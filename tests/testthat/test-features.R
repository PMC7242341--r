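test_that("a 19-channel segment yields sensors x bands x measures rows", {
  rec <- noiseRecording(fs = 128, durationS = 8, seed = 41)
  seg <- selectAwakeSegment(rec, 4, seed = 1)
  cfg <- runConfig(measures = c("SampE", "TT", "Lmax", "Lmean"),
                   analysisSamples = 200, durationS = 4)
  ft <- featuresForSegment(seg, cfg)
  expect_identical(nrow(ft), 19L * 7L * 4L)
  expect_setequal(unique(ft$measure), c("SampE", "TT", "Lmax", "Lmean"))
  expect_setequal(unique(ft$sensor), standardMontage()@allSensors)
  expect_identical(unique(ft$region[ft$sensor == "Cz"]), "CT")
  expect_identical(unique(ft$region[ft$sensor == "O1"]), "nonCT")
  # band annotations carry the dyadic edges
  expect_equal(sort(unique(ft$band_high_hz)), c(1, 2, 4, 8, 16, 32, 64))
})

test_that("feature extraction is deterministic", {
  rec <- noiseRecording(fs = 128, durationS = 8, seed = 42)
  seg <- selectAwakeSegment(rec, 4, seed = 5)
  cfg <- runConfig(measures = c("SampE", "Lmax"), analysisSamples = 200,
                   durationS = 4)
  expect_identical(featuresForSegment(seg, cfg),
                   featuresForSegment(seg, cfg))
})

test_that("an undefined band produces a reasoned missing row, not an abort", {
  rec <- noiseRecording(fs = 128, durationS = 8, seed = 43)
  rec@data[3, ] <- 7            # constant channel: SampEn undefined
  seg <- selectAwakeSegment(rec, 4, seed = 1)
  cfg <- runConfig(measures = "SampE", analysisSamples = 200,
                   durationS = 4)
  ft <- featuresForSegment(seg, cfg)
  expect_identical(nrow(ft), 19L * 7L)
  bad <- ft[ft$sensor == channelLabels(rec)[3], ]
  expect_true(all(is.na(bad$value)))
  expect_true(all(nzchar(bad$reason)))
  good <- ft[ft$sensor != channelLabels(rec)[3], ]
  expect_true(all(!is.na(good$value)))
})

test_that("montage coverage is enforced unless missing sensors are allowed", {
  rec <- noiseRecording(fs = 128, durationS = 8, seed = 44)
  drop <- which(channelLabels(rec) == "Pz")
  rec2 <- EEGRecording("s1", "case", 128, channelLabels(rec)[-drop],
                       signalData(rec)[-drop, ], normalize = FALSE)
  seg <- selectAwakeSegment(rec2, 4, seed = 1)
  cfg <- runConfig(measures = "SampE", analysisSamples = 200,
                   durationS = 4)
  expect_error(featuresForSegment(seg, cfg), "Pz")
  cfgA <- runConfig(measures = "SampE", analysisSamples = 200,
                    durationS = 4, allowMissing = TRUE)
  expect_warning(featuresForSegment(seg, cfgA), "Pz")
  ft <- suppressWarnings(featuresForSegment(seg, cfgA))
  expect_identical(nrow(ft), 18L * 7L)
})

test_that("non-montage channels (ECG) are excluded from extraction", {
  rec <- noiseRecording(fs = 128, durationS = 8, seed = 45)
  rec2 <- EEGRecording("s1", "case", 128, c(channelLabels(rec), "ECG"),
                       rbind(signalData(rec), rnorm(1024)),
                       normalize = FALSE)
  seg <- selectAwakeSegment(rec2, 4, seed = 1)
  cfg <- runConfig(measures = "SampE", analysisSamples = 200,
                   durationS = 4)
  ft <- featuresForSegment(seg, cfg)
  expect_false("ECG" %in% ft$sensor)
  expect_identical(nrow(ft), 19L * 7L)
})

test_that("feature tables round-trip through CSV with empty missing fields", {
  rec <- noiseRecording(fs = 128, durationS = 8, seed = 46)
  rec@data[1, ] <- 1
  seg <- selectAwakeSegment(rec, 4, seed = 1)
  ft <- featuresForSegment(seg, runConfig(measures = "SampE",
                                          analysisSamples = 200,
                                          durationS = 4))
  f <- tempfile(fileext = ".csv")
  writeFeatureTable(ft, f, configHash = "abcd1234")
  expect_match(readLines(f, n = 1), "config_hash: abcd1234")
  back <- readFeatureTable(f)
  expect_equal(back$value, ft$value)
  expect_identical(back$sensor, ft$sensor)
})
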