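# Paradigm definitions and stimulus schedules.

# Fixed pseudo-random condition order for the social selectivity paradigm.
# The published order is not available; alternating pairs are shipped as the
# package default and can be overridden via trialSequence=.
.SOCIAL_DEFAULT_ORDER <- rep(c("V", "V", "N", "N"), 4)

.HAND_EPOCHS <- rep(c("Fam1", "Fam2", "Fam3", "novel", "post"), each = 5)
.HAND_SPEAKERS <- rep(c("female", "male", "female"), c(15, 5, 5))

#' Construct a paradigm specification
#'
#' @param name `"social_selectivity"` or `"hand"` (habituation and novelty
#'   detection).
#' @param trialSequence optional override of the per-trial condition order
#'   (social paradigm only; must keep 8 V + 8 N).
#' @return A [ParadigmSpec-class].
#' @examples
#' paradigmSpec("social_selectivity")
#' paradigmSpec("hand")
#' @export
paradigmSpec <- function(name = c("social_selectivity", "hand"),
                         trialSequence = NULL) {
  name <- match.arg(name)
  if (name == "social_selectivity") {
    new("ParadigmSpec",
        name = name,
        trialDuration = 8,
        baselineRange = c(10, 12),
        trialSequence = if (is.null(trialSequence)) .SOCIAL_DEFAULT_ORDER
                        else as.character(trialSequence),
        speaker = character(0),
        blockAverageRange = c(-4, 20),
        requiredConditions = c("N", "V"))
  } else {
    new("ParadigmSpec",
        name = name,
        trialDuration = 8,
        baselineRange = c(10, 10),
        trialSequence = .HAND_EPOCHS,
        speaker = .HAND_SPEAKERS,
        blockAverageRange = c(-4, 18),
        requiredConditions = c("Fam1", "Fam3", "novel"))
  }
}

#' Generate a stimulus event schedule for a paradigm
#'
#' Lays out trial onsets with silent baseline periods between trials: a
#' 10-12 s jittered baseline for the social selectivity paradigm (uniform
#' over the range) and a fixed 10-s baseline preceding each trial of the
#' habituation paradigm. The schedule is a pure function of
#' `(paradigm, seed)`.
#'
#' @param paradigm a [ParadigmSpec-class] or a paradigm name.
#' @param seed integer seed controlling the baseline jitter.
#' @return data.frame with columns onset, duration, condition (and speaker
#'   for the hand paradigm), onsets in seconds.
#' @examples
#' ev <- generateStimulusSchedule("social_selectivity", seed = 1)
#' table(ev$condition)
#' @export
generateStimulusSchedule <- function(paradigm, seed = 1L) {
  if (is.character(paradigm)) paradigm <- paradigmSpec(paradigm)
  stopifnot(is(paradigm, "ParadigmSpec"))
  n <- length(paradigm@trialSequence)
  baselines <- .withSeed(seed,
    runif(n, paradigm@baselineRange[1], paradigm@baselineRange[2]))
  # baseline precedes every trial (incl. the first, as a lead-in)
  onsets <- cumsum(baselines + c(0, rep(paradigm@trialDuration, n - 1)))
  ev <- data.frame(onset = onsets,
                   duration = rep(paradigm@trialDuration, n),
                   condition = paradigm@trialSequence,
                   stringsAsFactors = FALSE)
  if (length(paradigm@speaker)) ev$speaker <- paradigm@speaker
  ev
}
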