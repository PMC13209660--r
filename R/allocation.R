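# Sleep-stage trial allocation: assign each subject's trials to QS/AS
# groups per analysis, handling within-trial transitions and the
# continuous-block retention rules.

#' Label trials with their sleep stage
#'
#' Each trial gets the timeline stage covering its onset-to-offset span;
#' trials straddling a stage change are labelled `"mixed"` (and flagged)
#' and are excluded downstream; trials inside awake intervals are labelled
#' awake.
#'
#' @param events event data.frame (onset, duration, condition).
#' @param timeline a [SleepTimeline-class] covering all events.
#' @param valid logical motion-validity flag per trial (default all valid).
#' @return data.frame (one row per trial): index, condition, onset,
#'   duration, motionValid, stage, withinTrialTransition.
#' @export
labelTrials <- function(events, timeline, valid = rep(TRUE, nrow(events))) {
  stopifnot(nrow(events) == length(valid))
  if (max(events$onset + events$duration) > timelineDuration(timeline) + 1e-9)
    stop("timeline does not cover all events")
  stage <- vapply(seq_len(nrow(events)), function(k)
    stageAt(timeline, events$onset[k], events$onset[k] + events$duration[k]),
    character(1))
  data.frame(index = seq_len(nrow(events)),
             condition = events$condition,
             onset = events$onset, duration = events$duration,
             motionValid = valid,
             stage = stage,
             withinTrialTransition = stage == "mixed",
             stringsAsFactors = FALSE)
}

# trials usable for a sleep-stage analysis: one sleep stage, not mixed/awake
.sleepTrials <- function(trials) trials[trials$stage %in% c("QS", "AS"), ]

.allocation <- function(analysis, group, retained = integer(0),
                        reason = "") {
  list(analysis = analysis, group = group,
       retainedTrialIndices = retained, reason = reason)
}

#' Allocate a subject's social selectivity trials to a sleep-stage group
#'
#' Stage-constant subjects join their stage's group with all valid trials.
#' Subjects who changed stage are retained when some window of six
#' consecutive trials lies entirely in one sleep stage and contains at
#' least three valid N and three valid V trials; the earliest qualifying
#' window decides the group, and all valid trials of that stage are
#' retained (trials from the other stage are discarded). Otherwise the
#' subject is excluded.
#'
#' @param trials data.frame from [labelTrials()] (16 trials).
#' @return list with analysis, group (QS/AS/excluded), retained trial
#'   indices and a reason string.
#' @export
allocateSocial <- function(trials) {
  stopifnot(nrow(trials) == 16L)
  st <- .sleepTrials(trials)
  stages <- unique(st$stage)
  okCounts <- function(tr) {
    sum(tr$condition == "N" & tr$motionValid) >= 3L &&
      sum(tr$condition == "V" & tr$motionValid) >= 3L
  }
  if (length(unique(trials$stage)) == 1L && stages[1] %in% c("QS", "AS")) {
    # stage-constant subject: group membership; the >=3-valid-per-condition
    # rule is enforced downstream by block averaging
    keep <- st$index[st$motionValid]
    return(.allocation("social", stages[1], keep, "constant stage"))
  }
  for (i in 1:11) {
    win <- trials[i:(i + 5L), ]
    wstage <- unique(win$stage)
    if (length(wstage) == 1L && wstage %in% c("QS", "AS") && okCounts(win)) {
      keep <- trials$index[trials$stage == wstage & trials$motionValid]
      return(.allocation("social", wstage, keep,
                         sprintf("qualifying block %d-%d", i, i + 5L)))
    }
  }
  reason <- if (nrow(transitionsFromTrials(trials)) > 1L)
    "multiple transitions" else "no qualifying block"
  .allocation("social", "excluded", reason = reason)
}

# stage changes along the trial sequence (ignoring mixed labels)
transitionsFromTrials <- function(trials) {
  st <- trials$stage[trials$stage != "mixed"]
  if (!length(st)) return(data.frame(from = character(0), to = character(0)))
  r <- rle(st)
  if (length(r$values) < 2L)
    return(data.frame(from = character(0), to = character(0)))
  data.frame(from = head(r$values, -1), to = r$values[-1],
             stringsAsFactors = FALSE)
}

#' Allocate a subject's HaND trials to a sleep-stage group per analysis
#'
#' \describe{
#'   \item{fam1}{at least three valid Fam1 trials sharing one sleep stage.}
#'   \item{habituation}{one sleep stage across all of trials 1-15 (Fam1,
#'     Fam2, Fam3) plus at least three valid Fam1 and three valid Fam3
#'     trials.}
#'   \item{novelty}{a contiguous run of at least three valid Fam3 trials
#'     ending at trial 15, directly followed by at least three valid novel
#'     trials from trial 16, all in the same sleep stage (strict reading:
#'     no invalid or other-stage trial inside the run).}
#' }
#' A subject can contribute different stages to different analyses, but at
#' most one stage per analysis.
#'
#' @param trials data.frame from [labelTrials()] (25 trials, conditions
#'   Fam1/Fam2/Fam3/novel/post).
#' @param analysis which analysis to allocate for.
#' @return list with analysis, group (QS/AS/excluded), retained trial
#'   indices and a reason string.
#' @export
allocateHand <- function(trials,
                         analysis = c("fam1", "habituation", "novelty")) {
  stopifnot(nrow(trials) == 25L)
  analysis <- match.arg(analysis)
  if (analysis == "fam1") {
    f1 <- trials[trials$condition == "Fam1", ]
    for (stg in c("QS", "AS")) {
      hit <- f1$stage == stg & f1$motionValid
      if (sum(hit) >= 3L)
        return(.allocation("hand_fam1", stg, f1$index[hit],
                           "3+ valid Fam1 in one stage"))
    }
    return(.allocation("hand_fam1", "excluded",
                       reason = "no stage with 3 valid Fam1 trials"))
  }
  if (analysis == "habituation") {
    fam <- trials[trials$index <= 15L, ]
    stg <- unique(fam$stage)
    if (length(stg) != 1L || !stg %in% c("QS", "AS"))
      return(.allocation("hand_habituation", "excluded",
                         reason = "stage change during familiarization"))
    nF1 <- sum(fam$condition == "Fam1" & fam$motionValid)
    nF3 <- sum(fam$condition == "Fam3" & fam$motionValid)
    if (nF1 >= 3L && nF3 >= 3L)
      return(.allocation("hand_habituation", stg,
                         fam$index[fam$motionValid], "constant stage Fam1-Fam3"))
    return(.allocation("hand_habituation", "excluded",
                       reason = "too few valid Fam1/Fam3 trials"))
  }
  # novelty: >=3 valid Fam3 directly followed by >=3 valid novel, one stage
  for (stg in c("QS", "AS")) {
    usable <- trials$stage == stg & trials$motionValid
    fam3Run <- 0L
    for (k in 15:11) { if (usable[k]) fam3Run <- fam3Run + 1L else break }
    novRun <- 0L
    for (k in 16:20) { if (usable[k]) novRun <- novRun + 1L else break }
    if (fam3Run >= 3L && novRun >= 3L) {
      keep <- c((16L - fam3Run):15L, 16L:(15L + novRun))
      return(.allocation("hand_novelty", stg, keep,
                         "contiguous Fam3->novel run"))
    }
  }
  .allocation("hand_novelty", "excluded",
              reason = "no contiguous same-stage Fam3->novel run")
}

#' Build per-analysis sleep-stage group tables for a cohort
#'
#' Applies [labelTrials()] plus the allocation rules to every subject and
#' returns, per analysis, the QS and AS membership together with the
#' stage-constant-only subset used for data-quality comparisons (subjects
#' who remained in one sleep stage throughout the paradigm).
#'
#' @param cohort a cohort from [generateCohort()] (or a compatible list of
#'   subjects with `timeline` and `schedule` elements).
#' @param valid named list (by subject id) of per-trial validity flags;
#'   defaults to all-valid.
#' @return data.frame: subject, analysis, group, stageConstant, nRetained,
#'   retained (comma-separated indices), reason.
#' @export
buildAnalysisGroups <- function(cohort, valid = NULL) {
  paradigm <- cohort$paradigm
  analyses <- if (paradigm@name == "social_selectivity") "social"
              else c("fam1", "habituation", "novelty")
  rows <- list()
  for (sub in cohort$subjects) {
    v <- if (is.null(valid)) rep(TRUE, nrow(sub$schedule))
         else valid[[sub$subjectId]]
    timeline <- deriveTimeline(sub$sheet)
    trials <- labelTrials(sub$schedule, timeline, v)
    stageConstant <- length(unique(trials$stage)) == 1L &&
      trials$stage[1] %in% c("QS", "AS")
    for (an in analyses) {
      al <- if (an == "social") allocateSocial(trials)
            else allocateHand(trials, an)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sub$subjectId, analysis = al$analysis, group = al$group,
        stageConstant = stageConstant,
        nRetained = length(al$retainedTrialIndices),
        retained = paste(al$retainedTrialIndices, collapse = ","),
        reason = al$reason, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
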