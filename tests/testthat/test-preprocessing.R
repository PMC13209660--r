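# Fixtures: small arrays built in code; fs = 10 Hz throughout.

sine3d <- function(freqs1, freqs2 = freqs1, n = 600, fs = 10, amp = 0.01) {
  t <- (0:(n - 1)) / fs
  nC <- length(freqs1)
  x <- array(1, c(nC, 2, n))
  for (ch in seq_len(nC)) {
    x[ch, 1, ] <- 1 + amp * sin(2 * pi * freqs1[ch] * t)
    x[ch, 2, ] <- 1 + amp * sin(2 * pi * freqs2[ch] * t)
  }
  x
}

test_that("SCI is 1 for shared cardiac tones, 0-ish for independent noise, -1 for inverted", {
  x <- sine3d(2.5)
  expect_equal(scalpCouplingIndex(x, fs = 10)[1], 1, tolerance = 1e-6)

  x[1, 2, ] <- 2 - x[1, 2, ]   # sign-flipped copy
  expect_equal(scalpCouplingIndex(x, fs = 10)[1], -1, tolerance = 1e-6)

  set.seed(1)
  y <- array(1 + 0.01 * rnorm(2 * 4000), c(1, 2, 4000))
  expect_lt(abs(scalpCouplingIndex(y, fs = 10)[1]), 0.25)

  z <- array(1, c(1, 2, 600))  # constant: flagged as 0
  expect_equal(scalpCouplingIndex(z, fs = 10)[1], 0)
})

test_that("PSP separates a shared tone from broadband noise", {
  qc <- qcParams()
  tone <- peakSpectralPower(sine3d(2.5), qc, fs = 10)[1]
  expect_gt(tone, qc$pspThreshold)
  set.seed(2)
  noise <- array(1 + 0.01 * rnorm(2 * 4000), c(1, 2, 4000))
  expect_lt(peakSpectralPower(noise, qc, fs = 10)[1], qc$pspThreshold)
  expect_equal(peakSpectralPower(array(1, c(1, 2, 600)), qc, fs = 10)[1], 0)
})

test_that("dataset exclusion triggers strictly above 40% bad channels", {
  qc <- qcParams()
  good <- rep(0.9, 18); psp <- rep(0.5, 18)
  sci7 <- good; sci7[1:7] <- 0.1
  expect_true(assessDatasetQuality(sci7, psp, qc)$datasetOk)   # 7/18 = 38.9%
  sci8 <- good; sci8[1:8] <- 0.1
  r8 <- assessDatasetQuality(sci8, psp, qc)
  expect_false(r8$datasetOk)                                    # 8/18 = 44.4%
  expect_equal(r8$badChannels, 1:8)
  expect_true(assessDatasetQuality(good, psp, qc)$datasetOk)
})

test_that("optical density follows -ln(I/mean(I)) and is scale invariant", {
  x <- array(2, c(1, 2, 100))
  expect_equal(max(abs(intensityToOD(x))), 0)

  x[1, 1, 50] <- 1  # I0/2 at one sample (mean barely moves)
  od <- intensityToOD(x)
  expect_equal(od[1, 1, 50], log(2), tolerance = 0.02)

  y <- array(runif(200, 0.5, 2), c(1, 2, 100))
  expect_equal(intensityToOD(y * 7), intensityToOD(y), tolerance = 1e-12)
  bad <- y; bad[1, 1, 1] <- -1
  expect_error(intensityToOD(bad), "positive")
})

test_that("motion detection flags steps but not hemodynamic-scale drift", {
  n <- 800; t <- (0:(n - 1)) / 10
  flat <- array(0, c(1, 2, n))
  expect_false(any(detectMotionByChannel(flat, fs = 10)))

  step <- flat; step[1, , ] <- rep(5 * (seq_len(n) > 400), each = 2)
  m <- detectMotionByChannel(step, fs = 10)
  expect_true(any(m[1, ]))
  hit <- range(which(m[1, ]))
  expect_lte(abs(hit[1] - 400), 21)   # flag starts within tMotion+tMask
  expect_gte(hit[2], 400)

  slow <- flat
  slow[1, 1, ] <- 0.01 * sin(2 * pi * 0.05 * t)  # HRF-scale smooth drift
  slow[1, 2, ] <- slow[1, 1, ]
  expect_false(any(detectMotionByChannel(slow, fs = 10)))
})

test_that("trials are rejected only when >50% of channels show motion", {
  par <- paradigmSpec("social_selectivity")
  ev <- data.frame(onset = c(30, 70), duration = 8, condition = c("N", "V"))
  mask <- matrix(FALSE, 18, 1000)
  expect_true(all(rejectTrials(mask, ev, par, fs = 10)))

  mask10 <- mask; mask10[1:10, 320:340] <- TRUE   # 10/18 during trial 1
  expect_equal(rejectTrials(mask10, ev, par, fs = 10), c(FALSE, TRUE))

  mask9 <- mask; mask9[1:9, 320:340] <- TRUE      # 9/18 = exactly 50%
  expect_equal(rejectTrials(mask9, ev, par, fs = 10), c(TRUE, TRUE))
})

test_that("motion correction removes planted steps and preserves clean data", {
  n <- 1200; t <- (0:(n - 1)) / 10
  clean <- 0.005 * sin(2 * pi * 0.08 * t)
  od <- array(0, c(1, 2, n)); od[1, 1, ] <- clean; od[1, 2, ] <- clean

  # empty mask: untouched
  mask0 <- matrix(FALSE, 1, n)
  expect_equal(correctMotion(od, mask0, fs = 10), od)

  stepod <- od
  stepod[1, 1, ] <- clean + 5 * (seq_len(n) > 600)
  stepod[1, 2, ] <- stepod[1, 1, ]
  mask <- detectMotionByChannel(stepod, fs = 10)
  fixed <- correctMotion(stepod, mask, fs = 10)
  expect_identical(dim(fixed), dim(stepod))
  before <- max(abs(diff(stepod[1, 1, ])))
  after <- max(abs(diff(fixed[1, 1, ])))
  expect_lt(after, 0.2 * before)   # step excursion reduced by >= 80%
})

test_that("low-pass filter preserves DC and passband, kills 3 Hz", {
  n <- 1000; t <- (0:(n - 1)) / 10
  dc <- array(3.7, c(1, 2, n))
  expect_equal(lowpassFilter(dc, fs = 10), dc, tolerance = 1e-8)

  hi <- sin(2 * pi * 3 * t)
  out <- lowpassFilter(hi, fs = 10)
  expect_lt(max(abs(out[200:800])), 0.1)   # >= 90% attenuation

  lo <- sin(2 * pi * 0.05 * t)
  outlo <- lowpassFilter(lo, fs = 10)
  expect_equal(max(abs(outlo[200:800])), max(abs(lo[200:800])),
               tolerance = 0.05)
})

test_that("Beer-Lambert inversion is the exact inverse of the forward model", {
  cp <- conversionParams()
  n <- 200
  hbo <- 0.8 * sin(2 * pi * (0:(n - 1)) / 77)   # uM
  hbr <- -0.3 * cos(2 * pi * (0:(n - 1)) / 53)
  od <- array(0, c(1, 2, n))
  for (w in 1:2)
    od[1, w, ] <- (cp$extinction[w, "HbO"] * hbo +
                   cp$extinction[w, "HbR"] * hbr) / 1000 *
      cp$separation * cp$dpf[w]
  conc <- odToConcentration(od, cp)
  expect_equal(as.numeric(conc[1, 1, ]), hbo, tolerance = 1e-9)
  expect_equal(as.numeric(conc[1, 2, ]), hbr, tolerance = 1e-9)

  expect_equal(max(abs(odToConcentration(array(0, c(1, 2, 10)), cp))), 0)

  cp2 <- conversionParams(dpf = cp$dpf * 2)
  expect_equal(as.numeric(odToConcentration(od, cp2)[1, 1, ]), hbo / 2,
               tolerance = 1e-9)
})

test_that("block averages are baseline-referenced and average across trials", {
  par <- paradigmSpec("social_selectivity")
  ev <- sparseEvents(6)
  n <- (max(ev$onset) + 30) * 10
  const <- array(2.5, c(2, 2, n))
  blk <- blockAverage(const, ev, rep(TRUE, 6), par)
  expect_equal(max(abs(blk@traces$N)), 0, tolerance = 1e-9)
  expect_equal(unname(nValidTrials(blk)[c("N", "V")]), c(3L, 3L))

  # antisymmetric trials cancel
  t <- (0:(n - 1)) / 10
  sig <- array(0, c(1, 2, n))
  bump <- function(onset, sign) sign * exp(-0.5 * ((t - onset - 8) / 3)^2)
  sgn <- c(1, -1, 1, -1, 1, -1)
  for (k in 1:6) sig[1, 1, ] <- sig[1, 1, ] + bump(ev$onset[k], sgn[k])
  blk2 <- blockAverage(sig, ev[ev$condition == "N" | TRUE, ],
                       rep(TRUE, 6), par, requiredConditions = character(0))
  # N trials are 1,3,5 (all +1); V are 2,4,6 (all -1): equal magnitude
  expect_equal(max(blk2@traces$N[1, 1, ]), -min(blk2@traces$V[1, 1, ]),
               tolerance = 0.05)

  # fewer than 3 valid trials in a required condition raises the exclusion
  expect_error(blockAverage(const, ev, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
                            par),
               class = "nirsleep_subject_exclusion")
})

test_that("mean response integrates the analysis window correctly", {
  par <- paradigmSpec("social_selectivity")
  ev <- sparseEvents(6)
  n <- (max(ev$onset) + 30) * 10
  conc <- array(0, c(1, 2, n))
  blk <- blockAverage(conc, ev, rep(TRUE, 6), par,
                      requiredConditions = character(0))
  blk@traces$N[1, 1, ] <- 1.5   # constant on the whole window
  mr <- meanResponse(blk, c(8, 16))
  expect_equal(mr$value[mr$condition == "N" & mr$chromophore == "HbO"], 1.5)
  expect_error(meanResponse(blk, c(30, 40)), "empty")
})

test_that("noiseless planted responses survive the full conversion chain", {
  par <- paradigmSpec("social_selectivity")
  ev <- sparseEvents(6)
  tl <- timelineFor(ev)
  p <- subjectParams(channelGain = c(rep(1, 9), rep(0.5, 9)))
  rec <- simulateRecording(ev, tl, p, seed = 1, noiseOn = FALSE,
                           artifactsOn = FALSE)
  conc <- odToConcentration(lowpassFilter(intensityToOD(rec)))
  blk <- blockAverage(conc, recordingEvents(rec), rep(TRUE, 6), par)
  planted <- p$responseAmplitude$N[["QS"]] * p$channelGain
  peaks <- apply(blk@traces$N[, 1, ], 1, max)
  expect_equal(peaks, planted, tolerance = 0.02)
  peaksR <- apply(blk@traces$N[, 2, ], 1, min)
  expect_equal(peaksR, p$hbrRatio * planted, tolerance = 0.02)
})

test_that("stages preserve sample and channel counts", {
  ev <- sparseEvents(2)
  tl <- timelineFor(ev)
  rec <- simulateRecording(ev, tl, seed = 9)
  od <- intensityToOD(rec)
  expect_identical(dim(od), dim(recordingIntensity(rec)))
  mask <- detectMotionByChannel(od)
  expect_identical(dim(correctMotion(od, mask)), dim(od))
  expect_identical(dim(lowpassFilter(od)), dim(od))
  expect_identical(dim(odToConcentration(od)), dim(od))
  pc <- percentCleanData(mask)
  expect_gte(pc, 0); expect_lte(pc, 100)
})
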