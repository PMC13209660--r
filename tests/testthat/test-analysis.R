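test_that("ROI registry reproduces the predefined channel lists", {
  reg <- roiRegistry()
  expect_equal(reg$UK$social_NV$HbO, c(9L, 15L, 16L, 18L))
  expect_equal(reg$UK$social_NV$HbR, c(15L, 18L))
  expect_equal(reg$GM$social_NV$HbO, c(15L, 16L, 18L))
  expect_equal(reg$GM$social_NV$HbR, c(6L, 7L, 9L, 10L, 13L, 15L, 16L, 18L))
  expect_equal(reg$UK$fam1$HbO, c(4L, 7L))
  expect_equal(reg$UK$fam1$HbR, c(7L, 15L, 18L))
  expect_equal(reg$GM$fam1$HbO, c(1L, 4L, 7L, 13L))
  expect_equal(reg$GM$fam1$HbR, c(4L, 7L, 13L))
  expect_equal(reg$UK$nv_contrast$HbO, c(4L, 13L, 14L, 15L, 16L))
  expect_equal(reg$UK$nv_contrast$HbR,
               c(4L, 7L, 9L, 13L, 14L, 15L, 16L, 17L, 18L))
  expect_equal(reg$UK$habituation$HbO, c(4L, 7L))
  expect_equal(reg$UK$habituation$HbR, 7L)
  expect_equal(reg$GM$habituation$HbO, c(1L, 7L))
  expect_equal(reg$GM$habituation$HbR, c(4L, 7L, 13L))
  # all channel ids live on the 18-channel array
  for (cohort in reg) for (an in cohort) for (chans in an)
    expect_true(all(chans %in% 1:18))
})

test_that("ROI means average the selected channels only, order-invariantly", {
  resp <- data.frame(channel = rep(1:18, 2),
                     chromophore = rep(c("HbO", "HbR"), each = 18),
                     condition = "N", value = c(1:18, rep(0, 18)))
  expect_equal(roiMean(resp, 5L, "HbO", "N"), 5)
  expect_equal(roiMean(resp, c(1L, 3L), "HbO", "N"), 2)
  expect_equal(roiMean(resp, c(3L, 1L), "HbO", "N"), 2)
  expect_error(roiMean(resp[resp$channel != 4, ], c(4L, 7L), "HbO", "N"),
               "missing ROI channel")
})

test_that("ROI group comparison detects planted stage differences with high power", {
  params <- statsParams(nPermutations = 200, nBootstrap = 200)
  set.seed(101)
  rej <- replicate(200, {
    qs <- rnorm(16, 0.0, 0.5)
    as_ <- rnorm(15, 0.65, 0.5)   # planted contrast difference, d ~ 1.3
    roiGroupComparison(qs, as_, params = params)$pParametric < 0.05
  })
  expect_gte(mean(rej), 0.8)

  # Per-group outlier filtering shrinks the SD estimate, so the realised
  # level of filter-then-t at these n sits slightly above nominal
  # (~0.08 in large simulations); the null rate must stay in that regime.
  set.seed(102)
  rejNull <- replicate(400, {
    qs <- rnorm(16, 0, 0.5); as_ <- rnorm(15, 0, 0.5)
    roiGroupComparison(qs, as_, params = params)$pParametric < 0.05
  })
  expect_gte(mean(rejNull), 0.02)
  expect_lte(mean(rejNull), 0.12)

  # without filtering the test is exact at nominal level
  set.seed(103)
  rejPlain <- replicate(400, {
    qs <- rnorm(16, 0, 0.5); as_ <- rnorm(15, 0, 0.5)
    roiGroupComparison(qs, as_, params = params,
                       iqrFilterOn = FALSE)$pParametric < 0.05
  })
  expect_gte(mean(rejPlain), 0.02)
  expect_lte(mean(rejPlain), 0.08)
})

test_that("ROI comparison filters outliers per group and reports both p-values", {
  set.seed(7)
  qs <- c(rnorm(14, 0, 0.3), 50)   # one gross outlier
  as_ <- rnorm(15, 0.2, 0.3)
  out <- roiGroupComparison(qs, as_,
                            params = statsParams(nPermutations = 200,
                                                 nBootstrap = 200))
  expect_equal(out$nRemovedQS, 1)
  expect_true(is.finite(out$pPermutation) && is.finite(out$pParametric))
})

test_that("channel-wise analysis finds planted channels and gates contrasts", {
  set.seed(55)
  n <- 20
  hits <- 0; spurious <- 0
  for (rep in 1:25) {
    m <- matrix(rnorm(n * 18, 0, 0.3), n, 18)
    m[, c(4, 7)] <- m[, c(4, 7)] + 0.45      # planted response, d = 1.5
    res <- channelwiseAnalysis(list(HbO = m, HbR = -0.4 * m))
    sig <- which(res$activation$HbO$significant)
    if (all(c(4, 7) %in% sig)) hits <- hits + 1
    spurious <- spurious + length(setdiff(sig, c(4, 7)))
  }
  expect_gte(hits / 25, 0.8)
  expect_lte(spurious / 25, 1)
})

test_that("contrast tests run only on channels significant against baseline", {
  set.seed(66)
  n <- 18
  m <- matrix(rnorm(n * 18, 0, 0.3), n, 18)
  m[, 4] <- m[, 4] + 0.8
  contrast <- matrix(rnorm(n * 18, 0, 0.3), n, 18)
  res <- channelwiseAnalysis(list(HbO = m, HbR = -0.3 * m),
                             contrastResponses = list(HbO = contrast,
                                                      HbR = -0.3 * contrast))
  sig1 <- which(res$activation$HbO$significant)
  expect_true(all(res$contrast$HbO$channel %in% sig1))
  expect_false(any(setdiff(1:18, sig1) %in% res$contrast$HbO$channel))
})

test_that("null cohorts produce almost no significant channels under FDR", {
  set.seed(77)
  counts <- replicate(100, {
    m <- matrix(rnorm(20 * 18), 20, 18)
    sum(channelwiseAnalysis(list(HbO = m, HbR = m))$activation$HbO$significant)
  })
  expect_lt(mean(counts), 1)
})

test_that("activation calls follow chromophore direction rules", {
  act <- list(
    HbO = data.frame(channel = 1:3, t = c(3, 3, -3), p = 0.001, pAdj = 0.001,
                     significant = c(TRUE, TRUE, TRUE), direction = c(1, 1, -1)),
    HbR = data.frame(channel = 1:3, t = c(-3, 3, -3), p = 0.001, pAdj = 0.001,
                     significant = c(TRUE, TRUE, FALSE), direction = c(-1, 1, -1)))
  calls <- nirsleep:::.activationCalls(act)
  ch1 <- calls[calls$channel == 1, ]
  expect_true(all(ch1$activated))            # HbO up + HbR down: canonical
  expect_false(any(ch1$atypical))
  ch2 <- calls[calls$channel == 2, ]
  expect_true(all(ch2$atypical))             # both up: atypical, excluded
  expect_false(any(ch2$activated))
  ch3 <- calls[calls$channel == 3, ]
  expect_false(any(ch3$activated))           # HbO decrease alone: not activation
})

test_that("data-quality table compares stage-constant groups in report layout", {
  set.seed(88)
  n <- 30
  metrics <- data.frame(
    subject = sprintf("s%02d", 1:n),
    group = rep(c("AS", "QS"), each = n / 2),
    stageConstant = TRUE,
    pctClean = c(rnorm(n / 2, 95.5, 2.5), rnorm(n / 2, 99.5, 0.4)),
    nValid_N = c(rnorm(n / 2, 6, 1.2), rnorm(n / 2, 7.7, 1)),
    nValid_V = c(rnorm(n / 2, 7, 1), rnorm(n / 2, 7.4, 1)))
  tab <- dataQualityTable(metrics,
                          statsParams(nPermutations = 300, nBootstrap = 300))
  expect_equal(tab$metric, c("pctClean", "nValid_N", "nValid_V"))
  expect_true(all(c("meanA", "sdA", "meanB", "sdB", "statistic",
                    "pParametric", "effectSizeD", "dCiLow", "dCiHigh",
                    "pPermutation") %in% names(tab)))
  # planted lower clean fraction in AS: negative t with AS as group A
  expect_lt(tab$statistic[tab$metric == "pctClean"], 0)
  expect_lt(tab$pParametric[tab$metric == "pctClean"], 0.05)
  expect_error(dataQualityTable(metrics[metrics$group == "AS", ]), "empty")
})

test_that("the pipeline runs end to end, deterministically, conserving subjects", {
  cfg <- list(paradigm = "social_selectivity", nQS = 4, nAS = 4,
              observability = 1,
              stats = statsParams(nPermutations = 100, nBootstrap = 100))
  out1 <- runPipeline(cfg, seed = 21)
  ledger <- out1$ledger
  expect_equal(ledger$total,
               ledger$codability + ledger$datasetQuality +
                 ledger$tooFewTrials + ledger$analysed)
  expect_gte(ledger$analysed, 6)
  expect_equal(sort(unique(out1$allocations$analysis)), "social")
  expect_true(all(out1$qc$pctClean >= 0 & out1$qc$pctClean <= 100))

  out2 <- runPipeline(cfg, seed = 21)
  expect_identical(out1$qc, out2$qc)
  expect_identical(out1$allocations, out2$allocations)

  dir <- withr::local_tempdir()
  runPipeline(cfg, seed = 21, outDir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("manifest.csv", "qc.csv", "allocations.csv", "mean_responses.csv",
      "run_log.json")))))
})

test_that("cohort text formats round-trip through their readers", {
  ev <- generateStimulusSchedule("hand", seed = 2)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "events.tsv")
  writeEventsTSV(ev, f)
  back <- readEventsTSV(f)
  expect_equal(back$onset, ev$onset, tolerance = 1e-9)
  expect_equal(back$condition, ev$condition)

  tl <- sleepTimeline(c("QS", "AS", "AS"))
  sheet <- simulateCodingSheet(tl, seed = 1, subjectId = "s1")
  g <- file.path(dir, "coding.csv")
  writeCodingSheetCSV(sheet, g)
  back2 <- readCodingSheetCSV(g, "s1")
  expect_equal(back2@epochs$stage, sheet@epochs$stage)
  expect_equal(back2@epochs$score, sheet@epochs$score)
})
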