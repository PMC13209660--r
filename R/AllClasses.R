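#' @import methods
#' @importFrom stats aggregate approx coef lm median na.omit p.adjust pt
#'   quantile rbinom rnorm rpois runif sd setNames smooth.spline t.test var
#' @importFrom utils head tail read.csv write.csv
NULL

SLEEP_STAGES <- c("QS", "AS", "awake")
CHROMOPHORES <- c("HbO", "HbR")

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream: every seeded operation in the package is a pure function of its
# seed and leaves the global random state untouched.
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  expr
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
}

.restoreRNG <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    rm(".Random.seed", envir = .GlobalEnv)
}

#' ProbeLayout: geometry and acquisition constants of the fNIRS array
#'
#' Describes the bilateral frontal-temporal infant array: 18 channels
#' (9 per hemisphere), two near-infrared wavelengths, a fixed
#' source-detector separation and the sampling rate.
#'
#' @slot nChannels integer, number of measurement channels (default 18).
#' @slot wavelengths numeric of length 2, wavelengths in nm (780, 850).
#' @slot separation numeric, source-detector separation in cm.
#' @slot samplingRate numeric, sampling frequency in Hz.
#' @slot hemisphere character, hemisphere label per channel.
#' @export
setClass("ProbeLayout",
  representation(
    nChannels    = "integer",
    wavelengths  = "numeric",
    separation   = "numeric",
    samplingRate = "numeric",
    hemisphere   = "character"
  )
)

setValidity("ProbeLayout", function(object) {
  msg <- NULL
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (length(object@wavelengths) != 2L)
    msg <- c(msg, "exactly two wavelengths are required")
  if (object@separation <= 0) msg <- c(msg, "separation must be positive")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (length(object@hemisphere) != object@nChannels)
    msg <- c(msg, "hemisphere labels must match nChannels")
  if (is.null(msg)) TRUE else msg
})

#' Construct the default 18-channel infant probe layout
#'
#' @param nChannels number of channels; the default array has 18,
#'   partitioned 9/9 across hemispheres.
#' @param wavelengths the two laser wavelengths in nm.
#' @param separation source-detector separation in cm.
#' @param samplingRate sampling frequency in Hz.
#' @return A [ProbeLayout-class] object.
#' @examples
#' probeLayout()
#' @export
probeLayout <- function(nChannels = 18L, wavelengths = c(780, 850),
                        separation = 2, samplingRate = 10) {
  nChannels <- as.integer(nChannels)
  hemi <- rep(c("left", "right"), each = ceiling(nChannels / 2))[seq_len(nChannels)]
  new("ProbeLayout", nChannels = nChannels, wavelengths = wavelengths,
      separation = separation, samplingRate = samplingRate, hemisphere = hemi)
}

setMethod("show", "ProbeLayout", function(object) {
  cat("ProbeLayout:", object@nChannels, "channels,",
      paste(object@wavelengths, collapse = "/"), "nm,",
      object@separation, "cm separation,",
      object@samplingRate, "Hz\n")
})

#' ParadigmSpec: structure of one auditory block-design paradigm
#'
#' Encodes the timing and condition structure of the two paradigms:
#' \describe{
#'   \item{social_selectivity}{8 vocal (V) and 8 non-vocal (N) trials of 8 s
#'     in a fixed pseudo-random order, separated by silent baselines of
#'     10-12 s.}
#'   \item{hand}{habituation-and-novelty-detection: 25 spoken-sentence trials
#'     of 8 s, each preceded by a 10-s baseline; trials 1-15 female speaker
#'     (epochs Fam1/Fam2/Fam3), 16-20 male (novel), 21-25 female (post).}
#' }
#'
#' @slot name paradigm name.
#' @slot trialDuration trial duration in seconds.
#' @slot baselineRange min/max silent baseline duration in seconds.
#' @slot trialSequence ordered condition label per trial.
#' @slot speaker speaker label per trial (hand paradigm), else empty.
#' @slot blockAverageRange peristimulus window (tRange) in seconds.
#' @slot requiredConditions conditions that must retain >= 3 valid trials.
#' @export
setClass("ParadigmSpec",
  representation(
    name               = "character",
    trialDuration      = "numeric",
    baselineRange      = "numeric",
    trialSequence      = "character",
    speaker            = "character",
    blockAverageRange  = "numeric",
    requiredConditions = "character"
  )
)

setValidity("ParadigmSpec", function(object) {
  msg <- NULL
  if (object@name == "social_selectivity") {
    tab <- table(object@trialSequence)
    if (!identical(sort(names(tab)), c("N", "V")) || any(tab != 8L))
      msg <- c(msg, "social sequence must contain exactly 8 V and 8 N trials")
  }
  if (object@name == "hand") {
    if (length(object@trialSequence) != 25L)
      msg <- c(msg, "hand sequence must have 25 trials")
    if (!identical(as.integer(table(object@speaker)[c("female", "male")]),
                   c(20L, 5L)))
      msg <- c(msg, "hand speakers must partition 15/5/5 (female/male/female)")
  }
  if (diff(object@baselineRange) < 0)
    msg <- c(msg, "baselineRange must be nondecreasing")
  if (diff(object@blockAverageRange) <= 0)
    msg <- c(msg, "blockAverageRange must be increasing")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ParadigmSpec", function(object) {
  cat("ParadigmSpec '", object@name, "': ", length(object@trialSequence),
      " trials of ", object@trialDuration, " s, baseline ",
      paste(object@baselineRange, collapse = "-"), " s, tRange [",
      paste(object@blockAverageRange, collapse = ", "), "] s\n", sep = "")
})

#' SleepTimeline: stage intervals and transitions over a recording
#'
#' A timeline is built from contiguous 15-s behavioural epochs; consecutive
#' epochs with the same stage are merged into intervals, and every stage
#' change is recorded as a transition.
#'
#' @slot epochStage stage label (QS/AS/awake) per 15-s epoch.
#' @slot epochLength epoch length in seconds (15).
#' @slot intervals data.frame with start, end, stage.
#' @slot transitions data.frame with time, from, to.
#' @export
setClass("SleepTimeline",
  representation(
    epochStage  = "character",
    epochLength = "numeric",
    intervals   = "data.frame",
    transitions = "data.frame"
  )
)

setValidity("SleepTimeline", function(object) {
  msg <- NULL
  if (!all(object@epochStage %in% SLEEP_STAGES))
    msg <- c(msg, "epoch stages must be QS, AS or awake")
  iv <- object@intervals
  if (nrow(iv)) {
    if (any(abs(iv$start[-1] - iv$end[-nrow(iv)]) > 1e-9))
      msg <- c(msg, "intervals must partition the coded span")
    if (nrow(iv) > 1 && any(iv$stage[-1] == iv$stage[-nrow(iv)]))
      msg <- c(msg, "adjacent intervals must have different stages")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a sleep timeline from per-epoch stage labels
#'
#' @param stages character vector of QS/AS/awake labels, one per epoch.
#' @param epochLength epoch duration in seconds (15 by convention).
#' @return A [SleepTimeline-class].
#' @examples
#' sleepTimeline(c("QS", "QS", "AS", "AS"))
#' @export
sleepTimeline <- function(stages, epochLength = 15) {
  stages <- as.character(stages)
  r <- rle(stages)
  ends <- cumsum(r$lengths) * epochLength
  starts <- c(0, head(ends, -1))
  iv <- data.frame(start = starts, end = ends, stage = r$values,
                   stringsAsFactors = FALSE)
  if (nrow(iv) > 1) {
    tr <- data.frame(time = iv$start[-1],
                     from = iv$stage[-nrow(iv)],
                     to   = iv$stage[-1], stringsAsFactors = FALSE)
  } else {
    tr <- data.frame(time = numeric(0), from = character(0), to = character(0),
                     stringsAsFactors = FALSE)
  }
  new("SleepTimeline", epochStage = stages, epochLength = epochLength,
      intervals = iv, transitions = tr)
}

#' @describeIn SleepTimeline-class total coded duration in seconds.
#' @param object,x a `SleepTimeline`.
#' @export
setGeneric("timelineDuration", function(object) standardGeneric("timelineDuration"))
#' @rdname SleepTimeline-class
#' @export
setMethod("timelineDuration", "SleepTimeline", function(object)
  length(object@epochStage) * object@epochLength)

#' @rdname SleepTimeline-class
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))
#' @rdname SleepTimeline-class
#' @export
setMethod("intervals", "SleepTimeline", function(x) x@intervals)

#' @rdname SleepTimeline-class
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))
#' @rdname SleepTimeline-class
#' @export
setMethod("transitions", "SleepTimeline", function(x) x@transitions)

#' @rdname SleepTimeline-class
#' @export
setGeneric("epochStages", function(x) standardGeneric("epochStages"))
#' @rdname SleepTimeline-class
#' @export
setMethod("epochStages", "SleepTimeline", function(x) x@epochStage)

#' Stage covering a time interval
#'
#' Returns the stage covering `[from, to)`, or `"mixed"` if more than one
#' stage overlaps the span.
#'
#' @param timeline a [SleepTimeline-class].
#' @param from,to span in seconds.
#' @return A single stage label or "mixed".
#' @export
stageAt <- function(timeline, from, to = from) {
  iv <- timeline@intervals
  hit <- iv$end > from & iv$start < to | (from == to & iv$start <= from & iv$end > from)
  st <- unique(iv$stage[hit])
  if (length(st) == 0L) stop("span not covered by timeline")
  if (length(st) > 1L) "mixed" else st
}

setMethod("show", "SleepTimeline", function(object) {
  cat("SleepTimeline:", length(object@epochStage), "epochs of",
      object@epochLength, "s (", timelineDuration(object), "s );",
      nrow(object@transitions), "transition(s)\n")
  print(object@intervals)
})

#' CodingSheet: behavioural sleep-stage micro-coding of one recording
#'
#' One row per 15-s epoch with the coded stage, the set of behavioural
#' criteria that could be reliably observed, and the resulting codability
#' score (0-100).
#'
#' @slot subjectId subject identifier.
#' @slot epochs data.frame with start, stage, criteriaObserved
#'   (semicolon-separated names) and score columns.
#' @slot epochLength epoch length in seconds.
#' @export
setClass("CodingSheet",
  representation(
    subjectId   = "character",
    epochs      = "data.frame",
    epochLength = "numeric"
  )
)

setValidity("CodingSheet", function(object) {
  msg <- NULL
  ep <- object@epochs
  need <- c("start", "stage", "criteriaObserved", "score")
  if (!all(need %in% names(ep)))
    msg <- c(msg, paste("epochs needs columns:", paste(need, collapse = ", ")))
  else {
    if (any(ep$score < 0 | ep$score > 100))
      msg <- c(msg, "scores must lie in [0, 100]")
    if (nrow(ep) > 1 &&
        any(abs(diff(ep$start) - object@epochLength) > 1e-9))
      msg <- c(msg, "epochs must be contiguous")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CodingSheet", function(object) {
  cat("CodingSheet for", object@subjectId, ":", nrow(object@epochs),
      "epochs, mean score", round(mean(object@epochs$score), 1), "\n")
})

#' RawRecording: dual-wavelength intensity time series with events
#'
#' Raw (simulated or imported) continuous-wave fNIRS intensities in
#' arbitrary units, strictly positive, with the stimulus event list and the
#' probe layout. Intensities are stored as a 3-d array
#' `[channel x wavelength x time]`.
#'
#' @slot intensity numeric array `[channel x wavelength x time]`, > 0.
#' @slot events data.frame with onset, duration, condition columns.
#' @slot layout a [ProbeLayout-class].
#' @slot subjectId subject identifier.
#' @slot truth list of planted ground truth (synthetic recordings only):
#'   noiseless HbO/HbR concentration arrays and per-trial stage labels.
#' @export
setClass("RawRecording",
  representation(
    intensity = "array",
    events    = "data.frame",
    layout    = "ProbeLayout",
    subjectId = "character",
    truth     = "list"
  )
)

setValidity("RawRecording", function(object) {
  msg <- NULL
  d <- dim(object@intensity)
  if (length(d) != 3L) msg <- c(msg, "intensity must be channel x wavelength x time")
  else {
    if (d[1] != object@layout@nChannels)
      msg <- c(msg, "intensity channel dimension must match layout")
    if (d[2] != 2L) msg <- c(msg, "two wavelengths required")
    if (any(object@intensity <= 0)) msg <- c(msg, "intensity must be strictly positive")
  }
  ev <- object@events
  if (nrow(ev)) {
    if (is.unsorted(ev$onset)) msg <- c(msg, "events must be sorted by onset")
    span <- d[3] / object@layout@samplingRate
    if (any(ev$onset + ev$duration > span + 1e-9))
      msg <- c(msg, "event offsets must fall within the recording span")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "RawRecording", function(object) {
  d <- dim(object@intensity)
  cat("RawRecording", object@subjectId, ":", d[1], "channels x", d[2],
      "wavelengths x", d[3], "samples (",
      round(d[3] / object@layout@samplingRate, 1), "s ),",
      nrow(object@events), "events\n")
})

#' @rdname RawRecording-class
#' @param x a `RawRecording`.
#' @export
setGeneric("recordingEvents", function(x) standardGeneric("recordingEvents"))
#' @rdname RawRecording-class
#' @export
setMethod("recordingEvents", "RawRecording", function(x) x@events)

#' @rdname RawRecording-class
#' @export
setGeneric("recordingIntensity", function(x) standardGeneric("recordingIntensity"))
#' @rdname RawRecording-class
#' @export
setMethod("recordingIntensity", "RawRecording", function(x) x@intensity)

#' BlockAverage: trial-averaged chromophore traces per condition
#'
#' Baseline-referenced, linearly detrended, trial-averaged HbO/HbR
#' concentration traces (micromolar) over the paradigm's peristimulus window,
#' with valid-trial bookkeeping.
#'
#' @slot traces named list (one per condition) of arrays
#'   `[channel x chromophore x time]` in micromolar.
#' @slot timeAxis peristimulus times in seconds.
#' @slot nValidTrials named integer, valid trials per retained condition.
#' @slot validTrialIndices named list of retained trial indices.
#' @slot paradigm paradigm name.
#' @export
setClass("BlockAverage",
  representation(
    traces            = "list",
    timeAxis          = "numeric",
    nValidTrials      = "integer",
    validTrialIndices = "list",
    paradigm          = "character"
  )
)

setValidity("BlockAverage", function(object) {
  msg <- NULL
  if (length(object@traces) &&
      !identical(sort(names(object@traces)), sort(names(object@nValidTrials))))
    msg <- c(msg, "traces and nValidTrials must name the same conditions")
  if (length(object@nValidTrials) && any(object@nValidTrials < 3L))
    msg <- c(msg, "every retained condition needs >= 3 valid trials")
  for (tr in object@traces)
    if (dim(tr)[3] != length(object@timeAxis))
      msg <- c(msg, "trace length must match timeAxis")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "BlockAverage", function(object) {
  cat("BlockAverage (", object@paradigm, "): conditions ",
      paste(sprintf("%s[n=%d]", names(object@nValidTrials),
                    object@nValidTrials), collapse = ", "),
      "; t = [", min(object@timeAxis), ", ", max(object@timeAxis),
      "] s\n", sep = "")
})

#' @rdname BlockAverage-class
#' @param x a `BlockAverage`.
#' @export
setGeneric("blockTraces", function(x) standardGeneric("blockTraces"))
#' @rdname BlockAverage-class
#' @export
setMethod("blockTraces", "BlockAverage", function(x) x@traces)

#' @rdname BlockAverage-class
#' @export
setGeneric("nValidTrials", function(x) standardGeneric("nValidTrials"))
#' @rdname BlockAverage-class
#' @export
setMethod("nValidTrials", "BlockAverage", function(x) x@nValidTrials)
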