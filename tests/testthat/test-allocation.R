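test_that("trials are labelled with the covering stage, mixed on transitions", {
  ev <- sparseEvents(4)
  tl <- timelineFor(ev, "QS")
  tr <- labelTrials(ev, tl)
  expect_true(all(tr$stage == "QS"))
  expect_false(any(tr$withinTrialTransition))

  # transition at 60 s; trial spanning 56-64 s straddles it
  tl2 <- sleepTimeline(c(rep("QS", 4), rep("AS", 6)))
  ev2 <- data.frame(onset = c(20, 56, 100), duration = 8,
                    condition = c("N", "V", "N"))
  tr2 <- labelTrials(ev2, tl2)
  expect_equal(tr2$stage, c("QS", "mixed", "AS"))
  expect_true(tr2$withinTrialTransition[2])

  tl3 <- sleepTimeline(c("awake", "awake", "QS"))
  ev3 <- data.frame(onset = 5, duration = 8, condition = "N")
  expect_equal(labelTrials(ev3, tl3)$stage, "awake")

  expect_error(labelTrials(data.frame(onset = 5000, duration = 8,
                                      condition = "N"), tl),
               "cover")
})

test_that("social allocation handles constant, windowed and excluded cases", {
  conds <- rep(c("V", "V", "N", "N"), 4)

  allQ <- allocateSocial(trialTable(conds, rep("QS", 16)))
  expect_equal(allQ$group, "QS")
  expect_equal(length(allQ$retainedTrialIndices), 16L)

  # QS for trials 1-6 (with 3 N + 3 V valid inside), AS after
  st <- c(rep("QS", 6), rep("AS", 10))
  cd <- c("N", "V", "N", "V", "N", "V", rep(c("N", "V"), 5))
  win <- allocateSocial(trialTable(cd, st))
  expect_equal(win$group, "QS")
  expect_true(all(win$retainedTrialIndices <= 6))

  # repeated sleep-awake oscillation with no qualifying six-trial block
  osc <- rep(c("AS", "AS", "awake", "awake"), 4)
  expect_equal(allocateSocial(trialTable(conds, osc))$group, "excluded")
})

test_that("hand allocation follows the per-analysis retention rules", {
  conds <- handConditions()

  constant <- trialTable(conds, rep("AS", 25))
  expect_equal(allocateHand(constant, "fam1")$group, "AS")
  expect_equal(allocateHand(constant, "habituation")$group, "AS")
  expect_equal(allocateHand(constant, "novelty")$group, "AS")

  # QS through trial 15, AS after: habituation in QS, novelty excluded
  split15 <- trialTable(conds, c(rep("QS", 15), rep("AS", 10)))
  expect_equal(allocateHand(split15, "habituation")$group, "QS")
  expect_equal(allocateHand(split15, "novelty")$group, "excluded")

  # QS for Fam1 only, AS for Fam3+novel: fam1 in QS, novelty in AS,
  # habituation excluded (stage change inside familiarization)
  splitEarly <- trialTable(conds, c(rep("QS", 5), rep("AS", 20)))
  expect_equal(allocateHand(splitEarly, "fam1")$group, "QS")
  expect_equal(allocateHand(splitEarly, "novelty")$group, "AS")
  expect_equal(allocateHand(splitEarly, "habituation")$group, "excluded")

  # an invalid trial inside the Fam3->novel junction breaks "directly
  # followed" under the strict rule
  v <- rep(TRUE, 25); v[15] <- FALSE
  strict <- trialTable(conds, rep("QS", 25), valid = v)
  expect_equal(allocateHand(strict, "novelty")$group, "excluded")
})

test_that("allocation matches the brute-force oracle on random cohorts", {
  set.seed(20)
  for (i in 1:150) {
    tr <- randomSocialTrials()
    expect_identical(allocateSocial(tr)$group, oracleSocialGroup(tr),
                     info = paste("social case", i))
  }
  for (i in 1:150) {
    tr <- randomHandTrials()
    for (an in c("fam1", "habituation", "novelty"))
      expect_identical(allocateHand(tr, an)$group, oracleHandGroup(tr, an),
                       info = paste("hand case", i, an))
  }
})

test_that("retained trials are never mixed or awake, one group per analysis", {
  set.seed(33)
  for (i in 1:80) {
    tr <- randomSocialTrials()
    al <- allocateSocial(tr)
    expect_true(al$group %in% c("QS", "AS", "excluded"))
    if (length(al$retainedTrialIndices)) {
      st <- tr$stage[al$retainedTrialIndices]
      expect_true(all(st == al$group))
      expect_true(all(tr$motionValid[al$retainedTrialIndices]))
    }
    th <- randomHandTrials()
    for (an in c("fam1", "habituation", "novelty")) {
      alh <- allocateHand(th, an)
      if (alh$group != "excluded") {
        st <- th$stage[alh$retainedTrialIndices]
        expect_true(all(st == alh$group))
      }
    }
  }
})

test_that("group tables separate analysis groups from data-quality subsets", {
  cfg <- list(paradigm = "social_selectivity", nQS = 3, nAS = 3,
              nTransition = 2, noiseOn = FALSE, artifactsOn = FALSE,
              observability = 1)
  co <- generateCohort(cfg, seed = 8)
  groups <- buildAnalysisGroups(co)
  expect_equal(nrow(groups), 8L)
  const <- groups[groups$subject %in%
                    co$manifest$subject[co$manifest$plantedGroup != "transition"], ]
  expect_true(all(const$stageConstant))
  expect_identical(
    unname(setNames(const$group, const$subject)[
      co$manifest$subject[co$manifest$plantedGroup == "QS"]]),
    rep("QS", 3))
  trans <- groups[groups$subject %in%
                    co$manifest$subject[co$manifest$plantedGroup == "transition"], ]
  # transition subjects may still be analysed but never count as
  # stage-constant unless the chain happened to stay in one stage
  for (s in unique(trans$subject)) {
    st <- strsplit(co$manifest$epochStages[co$manifest$subject == s], ",")[[1]]
    expect_identical(unique(trans$stageConstant[trans$subject == s]),
                     length(unique(st)) == 1L && st[1] %in% c("QS", "AS"))
  }
})
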