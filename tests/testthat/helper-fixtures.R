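# Shared fixtures and independent oracles used across test files.

# Events with long inter-stimulus intervals so trial responses are fully
# separable (the HRF returns to baseline before the next baseline window).
sparseEvents <- function(nTrials = 6, isi = 40, conditions = c("N", "V")) {
  data.frame(onset = seq(isi, by = isi, length.out = nTrials),
             duration = 8,
             condition = rep(conditions, length.out = nTrials),
             stringsAsFactors = FALSE)
}

timelineFor <- function(events, stage = "QS", tail = 25) {
  n <- ceiling((max(events$onset + events$duration) + tail) / 15)
  sleepTimeline(rep(stage, n))
}

# quick trial table for allocation tests
trialTable <- function(conditions, stages, valid = NULL) {
  n <- length(conditions)
  if (is.null(valid)) valid <- rep(TRUE, n)
  data.frame(index = seq_len(n), condition = conditions,
             onset = seq(0, by = 20, length.out = n), duration = 8,
             motionValid = valid, stage = stages,
             withinTrialTransition = stages == "mixed",
             stringsAsFactors = FALSE)
}

handConditions <- function() rep(c("Fam1", "Fam2", "Fam3", "novel", "post"),
                                 each = 5)

# ---- independent brute-force allocation oracles -------------------------
# Naive re-derivations of the retention rules, written as direct loops over
# every possibility, used to cross-check the package implementation.

oracleSocialGroup <- function(trials) {
  if (length(unique(trials$stage)) == 1L && trials$stage[1] %in% c("QS", "AS"))
    return(trials$stage[1])
  for (start in 1:11) {
    idx <- start:(start + 5)
    stg <- trials$stage[idx]
    if (all(stg == "QS") || all(stg == "AS")) {
      nN <- 0; nV <- 0
      for (k in idx) {
        if (trials$motionValid[k] && trials$condition[k] == "N") nN <- nN + 1
        if (trials$motionValid[k] && trials$condition[k] == "V") nV <- nV + 1
      }
      if (nN >= 3 && nV >= 3) return(stg[1])
    }
  }
  "excluded"
}

oracleHandGroup <- function(trials, analysis) {
  usable <- function(stg) trials$stage == stg & trials$motionValid
  if (analysis == "fam1") {
    for (stg in c("QS", "AS"))
      if (sum(usable(stg)[1:5]) >= 3) return(stg)
    return("excluded")
  }
  if (analysis == "habituation") {
    stg <- unique(trials$stage[1:15])
    if (length(stg) == 1 && stg %in% c("QS", "AS") &&
        sum(usable(stg)[1:5]) >= 3 && sum(usable(stg)[11:15]) >= 3)
      return(stg)
    return("excluded")
  }
  # novelty: >=3 valid Fam3 directly followed by >=3 valid novel, one
  # stage; equivalently trials 13-18 all valid in that stage
  for (stg in c("QS", "AS"))
    if (all(usable(stg)[13:18])) return(stg)
  "excluded"
}

# random trial tables exercising every branch of the rules
randomSocialTrials <- function() {
  stages <- sample(c("QS", "AS", "awake", "mixed"), 16, replace = TRUE,
                   prob = c(0.4, 0.4, 0.1, 0.1))
  # sometimes stage-constant, sometimes a single mid-run switch
  u <- runif(1)
  if (u < 0.3) stages <- rep(sample(c("QS", "AS"), 1), 16)
  else if (u < 0.6) {
    cut <- sample(2:15, 1)
    stages <- c(rep("QS", cut), rep("AS", 16 - cut))
  }
  trialTable(rep(c("V", "V", "N", "N"), 4), stages,
             valid = runif(16) < 0.85)
}

randomHandTrials <- function() {
  u <- runif(1)
  if (u < 0.3) stages <- rep(sample(c("QS", "AS"), 1), 25)
  else if (u < 0.6) {
    cut <- sample(2:24, 1)
    stages <- c(rep(sample(c("QS", "AS"), 1), cut),
                rep(sample(c("QS", "AS", "awake"), 1), 25 - cut))
  } else stages <- sample(c("QS", "AS", "awake", "mixed"), 25, replace = TRUE,
                          prob = c(0.4, 0.4, 0.1, 0.1))
  trialTable(handConditions(), stages, valid = runif(25) < 0.85)
}
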