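test_that("channel signals are standardized mixtures and seed-deterministic", {
  x <- generateChannelSignal(256, 8, mixWeight = 0, seed = 5)
  expect_length(x, 2048)
  expect_gt(sd(x), 0.9)
  expect_lt(sd(x), 1.1)
  expect_identical(x, generateChannelSignal(256, 8, mixWeight = 0,
                                            seed = 5))
  expect_false(identical(x, generateChannelSignal(256, 8, mixWeight = 0,
                                                  seed = 6)))
  expect_error(generateChannelSignal(256, 8, mixWeight = 1), "mixWeight")
})

test_that("the injected deficit is confined to centrotemporal case channels", {
  spec <- syntheticCohortSpec(nCase = 3, nContrast = 3, jitterSD = 0,
                              seed = 2)
  plan <- cohortWeightPlan(spec)
  ct <- standardMontage()@ctSensors
  isCT <- plan$sensor %in% ct
  isCase <- plan$group == "case"
  expect_true(all(plan$weight[isCase & isCT] ==
                    spec@oscMix + spec@ctDeficit))
  expect_true(all(plan$weight[!(isCase & isCT)] == spec@oscMix))
  # with the deficit off, the whole plan is flat: no case/contrast asymmetry
  plan0 <- cohortWeightPlan(syntheticCohortSpec(nCase = 3, nContrast = 3,
                                                jitterSD = 0, ctDeficit = 0,
                                                seed = 2))
  expect_true(all(plan0$weight == spec@oscMix))
})

test_that("cohorts materialize as deterministic EDF files plus manifest", {
  spec <- syntheticCohortSpec(nCase = 2, nContrast = 2, durationS = 4,
                              seed = 9)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  c1 <- generateCohort(spec, dir = d1)
  c2 <- generateCohort(spec, dir = d2)
  expect_identical(nrow(c1$manifest), 4L)
  expect_true(all(file.exists(c1$manifest$edf_path)))
  for (r in c1$recordings) {
    expect_identical(nChannels(r), 19L)
    expect_identical(nSamples(r), as.integer(4 * 256))
  }
  # byte-identical regeneration
  for (i in 1:4)
    expect_identical(readBin(c1$manifest$edf_path[i], "raw", 1e6),
                     readBin(c2$manifest$edf_path[i], "raw", 1e6))
  m1 <- readCohortManifest(file.path(d1, "cohort.csv"))
  m2 <- readCohortManifest(file.path(d2, "cohort.csv"))
  expect_identical(m1[c("subject_id", "group")], m2[c("subject_id", "group")])
  expect_identical(basename(m1$edf_path), basename(m2$edf_path))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the complexity knob sweep is reproducible with one row per weight", {
  spec <- syntheticCohortSpec(seed = 4)
  k1 <- calibrateComplexityKnob(spec, "SampE", weights = c(0, 0.4, 0.8),
                                nSeeds = 3, nSamples = 1024)
  k2 <- calibrateComplexityKnob(spec, "SampE", weights = c(0, 0.4, 0.8),
                                nSeeds = 3, nSamples = 1024)
  expect_identical(nrow(k1), 3L)
  expect_identical(k1, k2)
})

test_that("more oscillation raises determinism in the recurrence plot", {
  spec <- syntheticCohortSpec(seed = 6)
  kd <- calibrateComplexityKnob(spec, "DET", weights = c(0, 0.4, 0.8),
                                nSeeds = 5, nSamples = 1024)
  expect_true(all(diff(kd$mean_value) > 0))
})

test_that("sample entropy of raw channels falls monotonically with the knob", {
  spec <- syntheticCohortSpec(seed = 5)
  kn <- calibrateComplexityKnob(spec, "SampE",
                                weights = c(0, 0.2, 0.4, 0.6, 0.8),
                                nSeeds = 20, nSamples = 7680)
  expect_equal(kn$n, rep(20, 5))
  expect_true(all(diff(kn$mean_value) < 0))
})
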