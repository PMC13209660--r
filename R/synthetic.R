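# Synthetic cohort generator: sleep timelines, coding sheets and raw
# dual-wavelength intensity recordings with planted hemodynamic responses.

#' Stage dynamics of the epoch-level sleep chain
#'
#' Parameters of the first-order Markov chain over \{QS, AS, awake\} that
#' drives simulated 15-s epoch sequences, plus the expected fraction of
#' behavioural criteria visible per epoch.
#'
#' @param initialProbs named probabilities for the initial stage (QS/AS).
#' @param transitionProbs 3x3 row-stochastic matrix over QS/AS/awake.
#' @param meanObservability expected fraction of criteria observable.
#' @return list of class `"StageDynamics"`.
#' @export
stageDynamics <- function(initialProbs = c(QS = 0.5, AS = 0.5),
                          transitionProbs = NULL,
                          meanObservability = 0.9) {
  if (is.null(transitionProbs)) {
    transitionProbs <- rbind(
      QS    = c(QS = 0.97, AS = 0.02, awake = 0.01),
      AS    = c(QS = 0.03, AS = 0.95, awake = 0.02),
      awake = c(QS = 0.02, AS = 0.08, awake = 0.90))
  }
  transitionProbs <- as.matrix(transitionProbs)
  if (any(abs(rowSums(transitionProbs) - 1) > 1e-8))
    stop("each row of the transition matrix must sum to 1")
  stopifnot(abs(sum(initialProbs) - 1) < 1e-8,
            meanObservability >= 0, meanObservability <= 1)
  structure(list(initialProbs = initialProbs,
                 transitionProbs = transitionProbs,
                 meanObservability = meanObservability),
            class = "StageDynamics")
}

#' Absorbing dynamics keeping a subject in one stage
#' @param stage stage to absorb in.
#' @param meanObservability expected fraction of criteria observable.
#' @return list of class `"StageDynamics"`.
#' @export
constantStageDynamics <- function(stage = c("QS", "AS", "awake"),
                                  meanObservability = 0.9) {
  stage <- match.arg(stage)
  p <- setNames(numeric(2), c("QS", "AS"))
  p[if (stage == "awake") "QS" else stage] <- 1
  tm <- diag(3); dimnames(tm) <- list(c("QS", "AS", "awake"),
                                      c("QS", "AS", "awake"))
  stageDynamics(initialProbs = p, transitionProbs = tm,
                meanObservability = meanObservability)
}

#' Subject-level forward-model parameters
#'
#' Defaults define the simulated study conditions: hemodynamic response
#' amplitudes (micromolar HbO) per condition and sleep stage, the HbR/HbO
#' ratio, per-epoch habituation decay, a double-gamma HRF, physiological and
#' instrument noise, and stage-dependent motion-artifact rates (active sleep
#' noisier than quiet sleep).
#'
#' @param responseAmplitude named list: per condition, a named numeric with
#'   QS and AS peak HbO amplitudes in micromolar. For the hand paradigm only
#'   Fam1 needs to be given; Fam2/Fam3/novel/post are derived via
#'   `habituationDecay` (novel and post stay at the Fam3 level: the study
#'   conditions include no group-level novelty response).
#' @param hbrRatio HbR amplitude as a (negative) multiple of HbO.
#' @param habituationDecay per-stage multiplicative amplitude factor applied
#'   per successive familiarization epoch.
#' @param hrf list: peak and undershoot-peak times (s), undershoot ratio,
#'   kernel duration (s).
#' @param noise list: cardiac/respiratory/drift amplitudes (optical-density
#'   units) and frequencies (Hz), relative white intensity noise, baseline
#'   intensity `I0`. The cardiac frequency lies inside the 1.5-3.5 Hz
#'   infant band used by channel QC.
#' @param artifactRatePerMin per-stage Poisson rate of motion artifacts.
#' @param channelGain per-channel multiplicative response gain.
#' @param hbrLag HbR delay relative to HbO, seconds.
#' @return list of class `"SubjectParams"`.
#' @export
subjectParams <- function(responseAmplitude = NULL,
                          hbrRatio = -0.35,
                          habituationDecay = c(QS = 0.95, AS = 0.15),
                          hrf = list(peak = 7, undershootPeak = 16,
                                     ratio = 1 / 6, duration = 25),
                          noise = list(cardiacFreq = 2.2, cardiacAmp = 0.008,
                                       respFreq = 0.4, respAmp = 0.003,
                                       driftFreq = 0.012, driftAmp = 0.003,
                                       whiteSd = 0.0015, I0 = 1),
                          artifactRatePerMin = c(QS = 0.4, AS = 1.5),
                          channelGain = rep(1, 18),
                          hbrLag = 0) {
  if (is.null(responseAmplitude)) {
    responseAmplitude <- list(
      V    = c(QS = 0.30, AS = 0.30),
      N    = c(QS = 0.50, AS = 0.40),
      Fam1 = c(QS = 0.15, AS = 0.62))
  }
  stopifnot(noise$cardiacFreq >= 1.5, noise$cardiacFreq <= 3.5)
  if (artifactRatePerMin["AS"] < artifactRatePerMin["QS"])
    warning("artifact rate in AS is expected to be >= rate in QS")
  structure(list(responseAmplitude = responseAmplitude, hbrRatio = hbrRatio,
                 habituationDecay = habituationDecay, hrf = hrf,
                 noise = noise, artifactRatePerMin = artifactRatePerMin,
                 channelGain = channelGain, hbrLag = hbrLag),
            class = "SubjectParams")
}

#' Double-gamma hemodynamic response function
#'
#' Canonical difference of two gamma densities, parameterised by peak and
#' undershoot-peak times. The infant HRF is not firmly established; the
#' 7-s peak default is a documented, configurable choice.
#'
#' @param t times in seconds (>= 0).
#' @param peak time to peak of the positive lobe, seconds.
#' @param undershootPeak time to peak of the undershoot, seconds.
#' @param ratio undershoot amplitude relative to the main lobe.
#' @return HRF values, peak-normalised to 1.
#' @export
hrfDoubleGamma <- function(t, peak = 7, undershootPeak = 16, ratio = 1 / 6) {
  a1 <- 6; b1 <- (a1 - 1) / peak
  a2 <- 12; b2 <- (a2 - 1) / undershootPeak
  g <- function(x, a, b) ifelse(x <= 0, 0, (b^a) * x^(a - 1) * exp(-b * x) / gamma(a))
  h <- g(t, a1, b1) - ratio * g(t, a2, b2)
  h / max(g(seq(0, 4 * peak, by = 0.01), a1, b1))
}

# Condition regressor: boxcar of the stimulus duration convolved with the
# HRF, peak-normalised so a planted amplitude A yields a peak of A.
.conditionRegressor <- function(nT, fs, onset, duration, hrf) {
  tker <- seq(0, hrf$duration, by = 1 / fs)
  ker <- hrfDoubleGamma(tker, hrf$peak, hrf$undershootPeak, hrf$ratio)
  box <- rep(1, max(1L, round(duration * fs)))
  resp <- as.numeric(stats::convolve(c(box, numeric(length(ker) - 1)),
                                     rev(ker), type = "open"))
  resp <- resp[seq_len(length(box) + length(ker) - 1)]
  pk <- max(abs(resp))
  if (pk > 0) resp <- resp / pk
  out <- numeric(nT)
  i0 <- round(onset * fs) + 1L
  idx <- i0:min(nT, i0 + length(resp) - 1L)
  out[idx] <- resp[seq_along(idx)]
  out
}

#' Simulate a sleep-stage timeline as a 15-s-epoch Markov chain
#'
#' @param nEpochs number of 15-s epochs (>= 1).
#' @param dynamics a [stageDynamics()].
#' @param seed integer seed.
#' @return A [SleepTimeline-class].
#' @examples
#' simulateSleepTimeline(8, constantStageDynamics("QS"), seed = 1)
#' @export
simulateSleepTimeline <- function(nEpochs, dynamics = stageDynamics(),
                                  seed = 1L) {
  stopifnot(nEpochs >= 1)
  stages <- .withSeed(seed, {
    states <- colnames(dynamics$transitionProbs)
    st <- character(nEpochs)
    st[1] <- sample(names(dynamics$initialProbs), 1,
                    prob = dynamics$initialProbs)
    if (nEpochs > 1) for (i in 2:nEpochs) {
      st[i] <- sample(states, 1,
                      prob = dynamics$transitionProbs[st[i - 1], ])
    }
    st
  })
  sleepTimeline(stages)
}

#' Simulate a behavioural coding sheet for a timeline
#'
#' Each criterion of the scheme is independently "observed" with probability
#' `meanObservability` per epoch; the epoch score is the summed weight of
#' the observed criteria, and the coded stage is the true timeline stage.
#'
#' @param timeline a [SleepTimeline-class].
#' @param scheme a [codingScheme()].
#' @param dynamics a [stageDynamics()] supplying `meanObservability`.
#' @param seed integer seed.
#' @param subjectId subject identifier.
#' @return A [CodingSheet-class].
#' @export
simulateCodingSheet <- function(timeline, scheme = codingScheme(),
                                dynamics = stageDynamics(), seed = 1L,
                                subjectId = "sim") {
  stages <- epochStages(timeline)
  nm <- scheme$criteria$name
  obs <- .withSeed(seed, vapply(seq_along(stages), function(i) {
    seen <- nm[runif(length(nm)) < dynamics$meanObservability]
    paste(seen, collapse = ";")
  }, character(1)))
  scores <- vapply(strsplit(obs, ";", fixed = TRUE), function(s)
    scoreEpoch(s[nzchar(s)], scheme), numeric(1))
  ep <- data.frame(start = (seq_along(stages) - 1) * timeline@epochLength,
                   stage = stages, criteriaObserved = obs, score = scores,
                   stringsAsFactors = FALSE)
  new("CodingSheet", subjectId = subjectId, epochs = ep,
      epochLength = timeline@epochLength)
}

# Amplitude for a condition in a sleep stage, applying habituation decay to
# the familiarization epochs. Trials during awake epochs evoke no modeled
# response.
.amplitudeFor <- function(condition, stage, params) {
  if (!stage %in% c("QS", "AS")) return(0)
  decay <- params$habituationDecay[[stage]]
  ra <- params$responseAmplitude
  base <- function(cond) if (cond %in% names(ra)) ra[[cond]][[stage]] else 0
  switch(condition,
         Fam1 = base("Fam1"),
         Fam2 = if ("Fam2" %in% names(ra)) base("Fam2") else base("Fam1") * decay,
         Fam3 = if ("Fam3" %in% names(ra)) base("Fam3") else base("Fam1") * decay^2,
         novel = if ("novel" %in% names(ra)) base("novel") else base("Fam1") * decay^2,
         post = if ("post" %in% names(ra)) base("post") else base("Fam1") * decay^2,
         base(condition))
}

#' Simulate a raw dual-wavelength fNIRS recording
#'
#' Forward model: condition regressors (boxcar convolved with a double-gamma
#' HRF) are scaled by the stage-dependent amplitude of the timeline stage at
#' each trial onset, with habituation decay across familiarization epochs;
#' HbR is a scaled (negative), optionally delayed copy of HbO. Concentrations
#' map to optical density via the extinction/DPF/separation forward model and
#' to intensity via \eqn{I = I_0 e^{-\Delta OD}}. Physiological noise
#' (cardiac, shared across wavelengths; respiratory; slow drift) is added in
#' OD space, white instrument noise and stage-dependent motion artifacts
#' (spikes and baseline steps, more frequent in active sleep) in intensity
#' space.
#'
#' @param schedule event data.frame from [generateStimulusSchedule()].
#' @param timeline a [SleepTimeline-class] covering the schedule.
#' @param params a [subjectParams()].
#' @param layout a [probeLayout()].
#' @param seed integer seed.
#' @param conversion a [conversionParams()] used as the forward model.
#' @param subjectId subject identifier.
#' @param noiseOn logical; disable to obtain the noiseless forward model.
#' @param artifactsOn logical; disable motion artifacts.
#' @return A [RawRecording-class] whose `truth` slot carries the planted
#'   noiseless concentrations and per-trial stages.
#' @export
simulateRecording <- function(schedule, timeline, params = subjectParams(),
                              layout = probeLayout(), seed = 1L,
                              conversion = conversionParams(),
                              subjectId = "sim", noiseOn = TRUE,
                              artifactsOn = TRUE) {
  fs <- layout@samplingRate
  dur <- timelineDuration(timeline)
  lastNeed <- max(schedule$onset + schedule$duration) + params$hrf$duration
  if (lastNeed > dur + 1e-9)
    stop("schedule (plus HRF tail) does not fit within the timeline duration")
  oldSeed <- .saveRNG()
  on.exit(.restoreRNG(oldSeed))
  set.seed(as.integer(seed))
  nT <- round(dur * fs)
  nC <- layout@nChannels
  tt <- (seq_len(nT) - 1) / fs

  # epoch index of each trial onset -> stage
  trialStage <- vapply(seq_len(nrow(schedule)), function(k)
    stageAt(timeline, schedule$onset[k], schedule$onset[k] + schedule$duration[k]),
    character(1))
  onsetStage <- vapply(schedule$onset, function(o) stageAt(timeline, o),
                       character(1))

  famSeen <- 0L
  base <- numeric(nT)
  amps <- numeric(nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    amps[k] <- .amplitudeFor(schedule$condition[k], onsetStage[k], params)
    if (amps[k] != 0)
      base <- base + amps[k] *
        .conditionRegressor(nT, fs, schedule$onset[k], schedule$duration[k],
                            params$hrf)
  }
  hbo <- outer(params$channelGain[seq_len(nC)], base)      # channel x time, uM
  lag <- round(params$hbrLag * fs)
  hbrBase <- if (lag > 0) c(numeric(lag), base[seq_len(nT - lag)]) else base
  hbr <- params$hbrRatio * outer(params$channelGain[seq_len(nC)], hbrBase)

  # forward MBLL: OD(lambda) = (eHbO*HbO + eHbR*HbR)/1000 * d * DPF(lambda)
  ext <- conversion$extinction
  dpf <- conversion$dpf
  sep <- conversion$separation
  od <- array(0, dim = c(nC, 2L, nT))
  for (w in 1:2)
    od[, w, ] <- (ext[w, "HbO"] * hbo + ext[w, "HbR"] * hbr) / 1000 * sep * dpf[w]

  nz <- params$noise
  if (noiseOn) {
    for (ch in seq_len(nC)) {
      phC <- runif(1, 0, 2 * pi); phR <- runif(1, 0, 2 * pi)
      card <- nz$cardiacAmp * sin(2 * pi * nz$cardiacFreq * tt + phC)
      resp <- nz$respAmp * sin(2 * pi * nz$respFreq * tt + phR)
      drift <- nz$driftAmp * sin(2 * pi * nz$driftFreq * tt + runif(1, 0, 2 * pi))
      for (w in 1:2) {
        wscale <- c(1, 0.85)[w]
        od[ch, w, ] <- od[ch, w, ] + wscale * (card + resp) + drift
      }
    }
  }

  if (artifactsOn) {
    iv <- intervals(timeline)
    for (r in seq_len(nrow(iv))) {
      st <- iv$stage[r]
      rate <- if (st %in% names(params$artifactRatePerMin))
        params$artifactRatePerMin[[st]] else mean(params$artifactRatePerMin)
      span <- iv$end[r] - iv$start[r]
      nArt <- rpois(1, rate * span / 60)
      if (nArt == 0) next
      for (a in seq_len(nArt)) {
        t0 <- runif(1, iv$start[r], iv$end[r])
        chans <- sample(nC, max(1L, round(runif(1, 0.2, 0.7) * nC)))
        amp <- runif(1, 0.6, 1.5) * sample(c(-1, 1), 1)
        if (runif(1) < 0.6) {                     # spike
          width <- runif(1, 0.2, 0.6)
          bump <- amp * exp(-0.5 * ((tt - t0) / (width / 2))^2)
          for (w in 1:2) od[chans, w, ] <- od[chans, w, ] +
              matrix(bump, length(chans), nT, byrow = TRUE)
        } else {                                  # baseline step
          stepv <- amp * (tt >= t0)
          for (w in 1:2) od[chans, w, ] <- od[chans, w, ] +
              matrix(stepv, length(chans), nT, byrow = TRUE)
        }
      }
    }
  }

  inten <- nz$I0 * exp(-od)
  if (noiseOn && nz$whiteSd > 0)
    inten <- inten * (1 + array(rnorm(length(inten), 0, nz$whiteSd), dim(inten)))
  if (any(inten <= 0))
    stop("negative or zero intensity produced; noise amplitudes are misconfigured")

  new("RawRecording", intensity = inten, events = schedule, layout = layout,
      subjectId = subjectId,
      truth = list(hbo = hbo, hbr = hbr, trialStage = trialStage,
                   onsetStage = onsetStage, amplitudes = amps))
}

#' Generate a synthetic cohort
#'
#' Produces one recording, event schedule, sleep timeline and coding sheet
#' per subject, together with a manifest of the planted ground truth. Group
#' sizes, stage dynamics and effect sizes come from `config`; everything is
#' a pure function of `(config, seed)`.
#'
#' @param config list with elements: `paradigm` (name or
#'   [ParadigmSpec-class]), `nQS`, `nAS` (stage-constant subjects),
#'   `nTransition` (subjects following the default switching dynamics),
#'   `params` (a [subjectParams()] template), `scheme`, `observability`,
#'   `lowObsFraction` (fraction of subjects simulated with poor visibility,
#'   observability 0.3), `amplitudeBetweenSd` (between-subject SD, uM, of a
#'   global response-gain perturbation), `noiseOn`, `artifactsOn`.
#' @param seed integer master seed.
#' @return list with `subjects` (list of per-subject lists: recording,
#'   schedule, timeline, sheet, plantedGroup) and `manifest` (data.frame).
#' @export
generateCohort <- function(config, seed = 1L) {
  cf <- config
  cf$paradigm <- cf$paradigm %||% "social_selectivity"
  par <- if (is.character(cf$paradigm)) paradigmSpec(cf$paradigm) else cf$paradigm
  cf$nQS <- cf$nQS %||% 0L; cf$nAS <- cf$nAS %||% 0L
  cf$nTransition <- cf$nTransition %||% 0L
  cf$params <- cf$params %||% subjectParams()
  cf$scheme <- cf$scheme %||% codingScheme()
  cf$observability <- cf$observability %||% 0.9
  cf$lowObsFraction <- cf$lowObsFraction %||% 0
  cf$amplitudeBetweenSd <- cf$amplitudeBetweenSd %||% 0
  cf$noiseOn <- cf$noiseOn %||% TRUE
  cf$artifactsOn <- cf$artifactsOn %||% TRUE

  groups <- c(rep("QS", cf$nQS), rep("AS", cf$nAS),
              rep("transition", cf$nTransition))
  n <- length(groups)
  oldSeed <- .saveRNG()
  on.exit(.restoreRNG(oldSeed))
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n * 3L)
  lowObs <- runif(n) < cf$lowObsFraction

  subjects <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("sub-%03d", i)
    schedule <- generateStimulusSchedule(par, seed = seeds[i])
    nEpochs <- ceiling((max(schedule$onset + schedule$duration) +
                          cf$params$hrf$duration) / 15)
    obsi <- if (lowObs[i]) 0.3 else cf$observability
    dyn <- if (groups[i] == "transition")
      stageDynamics(meanObservability = obsi)
    else constantStageDynamics(groups[i], meanObservability = obsi)
    timeline <- simulateSleepTimeline(nEpochs, dyn, seed = seeds[n + i])
    sheet <- simulateCodingSheet(timeline, cf$scheme, dyn,
                                 seed = seeds[n + i], subjectId = sid)
    pars <- cf$params
    if (cf$amplitudeBetweenSd > 0) {
      set.seed(seeds[2L * n + i])
      shift <- rnorm(1, 0, cf$amplitudeBetweenSd)
      pars$responseAmplitude <- lapply(pars$responseAmplitude,
                                       function(a) pmax(a + shift, 0))
    }
    rec <- simulateRecording(schedule, timeline, pars, seed = seeds[2L * n + i],
                             subjectId = sid, noiseOn = cf$noiseOn,
                             artifactsOn = cf$artifactsOn)
    subjects[[i]] <- list(subjectId = sid, recording = rec,
                          schedule = schedule, timeline = timeline,
                          sheet = sheet, plantedGroup = groups[i])
    rows[[i]] <- data.frame(
      subject = sid, plantedGroup = groups[i], paradigm = par@name,
      observability = obsi,
      epochStages = paste(epochStages(timeline), collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(subjects = subjects, manifest = do.call(rbind, rows),
       paradigm = par, config = cf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
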