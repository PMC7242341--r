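test_that("group curves aggregate per band with normal-approximation CIs", {
  # two subjects with identical values: mean = value, zero half-width
  tab <- rbind(
    featureTableFromAUC(list(case_CT = c(2, 2))),
    featureTableFromAUC(list(contrast_CT = c(1, 3))))
  tab$subject_id[tab$group == "case"] <-
    rep(c("case01", "case02"), each = 2)
  tab$sensor[tab$group == "case"] <- "C3"
  cv <- multiscaleGroupCurve(tab, "SampE", "C3", "case")
  expect_equal(cv@bandMeans, c(2, 2))
  expect_equal(cv@ciHalfWidth, c(0, 0))
  expect_identical(cv@nPerBand, c(2L, 2L))
  # exact CI arithmetic against the closed form
  tab$subject_id[tab$group == "contrast"] <-
    rep(c("contrast01", "contrast02"), each = 2)
  tab$sensor[tab$group == "contrast"] <- "C3"
  cv2 <- multiscaleGroupCurve(tab, "SampE", "C3", "contrast")
  expect_equal(cv2@bandMeans, c(2, 2))
  expect_equal(cv2@ciHalfWidth, rep(1.96 * sd(c(1, 3)) / sqrt(2), 2))
  cvt <- multiscaleGroupCurve(tab, "SampE", "C3", "contrast", ci = "t")
  expect_equal(cvt@ciHalfWidth, rep(qt(0.975, 1) * sd(c(1, 3)) / sqrt(2), 2))
})

test_that("single-subject curves warn and degenerate bands error by index", {
  tab <- featureTableFromAUC(list(case_CT = 4))
  expect_warning(cv <- multiscaleGroupCurve(tab, "SampE", "C3", "case"),
                 "n = 1")
  expect_equal(cv@ciHalfWidth, c(0, 0))
  tab2 <- tab
  tab2$value[tab2$band_index == 2] <- NA
  expect_error(suppressWarnings(
    multiscaleGroupCurve(tab2, "SampE", "C3", "case")), "band 2")
})

test_that("curve means track a known population mean (sampling check)", {
  mu <- c(1, 2, 3, 4, 5)
  hit <- 0; tries <- 0
  for (s in 1:25) {
    set.seed(s)
    vals <- matrix(rnorm(20 * 5, rep(mu, each = 20), 0.5), 20, 5)
    tab <- do.call(rbind, lapply(1:20, function(i)
      data.frame(subject_id = sprintf("case%02d", i), group = "case",
                 sensor = "C3", region = "CT", band_index = 1:5,
                 band_low_hz = 0, band_high_hz = 1, measure = "SampE",
                 value = vals[i, ], reason = NA_character_)))
    cv <- multiscaleGroupCurve(tab, "SampE", "C3", "case")
    sem <- 0.5 / sqrt(20)
    hit <- hit + sum(abs(cv@bandMeans - mu) <= 3 * sem)
    tries <- tries + 5
  }
  expect_gte(hit / tries, 0.95)
})

test_that("trapezoidal AUC matches hand sums, interpolates and truncates", {
  expect_equal(curveAUC(rep(3, 7)), 18)          # 6 * c
  expect_equal(curveAUC(c(0, 1)), 0.5)
  expect_equal(curveAUC(c(1, 3, 2)), 4.5)
  expect_equal(curveAUC(c(1, NA, 3)), 4)         # interior gap -> 1,2,3
  expect_warning(a <- curveAUC(c(NA, 1, 3)), "truncated")
  expect_equal(a, 2)
  expect_error(curveAUC(c(NA, 1, NA)), "at least 2")
  # linearity on complete curves
  set.seed(3)
  v <- rnorm(7); w <- rnorm(7)
  expect_equal(curveAUC(2 * v + 5 * w), 2 * curveAUC(v) + 5 * curveAUC(w))
})

test_that("the four-cell ANOVA recovers hand-computed sums of squares", {
  tab <- featureTableFromAUC(list(case_CT = c(1, 2), case_nonCT = c(3, 4),
                                  contrast_CT = c(1, 2),
                                  contrast_nonCT = c(3, 4)))
  rs <- regionANOVA(tab, "SampE")
  # grand mean 2.5; SSB = 8, SSW = 2 -> F = (8/3)/(2/4) = 16/3
  expect_equal(fStatistic(rs), 16 / 3)
  expect_identical(rs@dfBetween, 3L)
  expect_identical(rs@dfWithin, 4L)
  expect_equal(pValue(rs), pf(16 / 3, 3, 4, lower.tail = FALSE))
  expect_equal(unname(cellMeans(rs)),
               c(1.5, 3.5, 1.5, 3.5))
  # equal cells: F = 0, p = 1
  eq <- featureTableFromAUC(list(case_CT = 1:3, case_nonCT = 1:3,
                                 contrast_CT = 1:3, contrast_nonCT = 1:3))
  rs0 <- regionANOVA(eq, "SampE")
  expect_equal(fStatistic(rs0), 0)
  expect_equal(pValue(rs0), 1)
})

test_that("ANOVA errors name empty cells and reject all-constant cells", {
  tab <- featureTableFromAUC(list(case_CT = c(1, 2), case_nonCT = c(3, 4),
                                  contrast_CT = c(1, 2)))
  expect_error(regionANOVA(tab, "SampE"), "contrast_nonCT")
  con <- featureTableFromAUC(list(case_CT = c(1, 1), case_nonCT = c(2, 2),
                                  contrast_CT = c(1, 1),
                                  contrast_nonCT = c(2, 2)))
  expect_error(regionANOVA(con, "SampE"), "zero within-cell variance")
})

test_that("sum-of-squares identity and F invariances hold on random cells", {
  for (s in 1:10) {
    set.seed(s)
    tab <- featureTableFromAUC(list(case_CT = rnorm(6, 1),
                                    case_nonCT = rnorm(8, 2),
                                    contrast_CT = rnorm(7),
                                    contrast_nonCT = rnorm(9, 0.5)))
    rs <- regionANOVA(tab, "SampE")
    obs <- unlist(regionCells(rs))
    sst <- sum((obs - mean(obs))^2)
    ssb <- sum(vapply(regionCells(rs), function(v)
      length(v) * (mean(v) - mean(obs))^2, 0))
    ssw <- sum(vapply(regionCells(rs), function(v)
      sum((v - mean(v))^2), 0))
    expect_lt(abs(sst - (ssb + ssw)) / sst, 1e-9)
    # F from the hand-computed decomposition equals the fitted one
    expect_equal(fStatistic(rs),
                 (ssb / 3) / (ssw / (length(obs) - 4)))
    # shift and positive rescale leave F unchanged
    tabS <- tab; tabS$value <- 3 * tab$value + 11
    expect_equal(fStatistic(regionANOVA(tabS, "SampE")), fStatistic(rs))
  }
})

test_that("heatmap table averages AUCs per sensor and group", {
  allCells <- list(case_CT = rep(1, 14), case_nonCT = rep(1, 24),
                   contrast_CT = rep(1, 14), contrast_nonCT = rep(1, 24))
  hm <- heatmapTable(featureTableFromAUC(allCells), "SampE")
  expect_identical(nrow(hm), 38L)
  expect_identical(sum(hm$group == "case"), 19L)
  expect_true(all(hm$mean_auc == 1))
  # cell values equal an independent group-by aggregation
  set.seed(8)
  cells <- list(case_CT = rnorm(14), case_nonCT = rnorm(24),
                contrast_CT = rnorm(14), contrast_nonCT = rnorm(24))
  tab <- featureTableFromAUC(cells)
  hm2 <- heatmapTable(tab, "SampE")
  auc <- subjectSensorAUC(tab, "SampE")
  agg <- aggregate(auc ~ sensor + group, auc, mean)
  m <- merge(hm2, agg, by = c("sensor", "group"))
  expect_equal(m$mean_auc, m$auc)
  # a sensor with no observations errors unless allowed
  few <- featureTableFromAUC(list(case_CT = 1:2, case_nonCT = 1:2,
                                  contrast_CT = 1:2, contrast_nonCT = 1:2))
  expect_error(heatmapTable(few, "SampE"), "no AUC")
  hm3 <- suppressWarnings(heatmapTable(few, "SampE", allowMissing = TRUE))
  expect_lt(nrow(hm3), 38L)
})
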