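# ROI-based and channel-wise sleep-stage analyses.

#' Registry of predefined regions of interest
#'
#' Channel lists (per cohort, analysis and chromophore) imported as fixed
#' inputs from the full-cohort activation analyses that defined them; they
#' are not recomputed here.
#'
#' @return nested list: `registry[[cohort]][[analysis]][[chromophore]]` ->
#'   integer channel ids (1-18). Cohorts: `UK`, `GM`. Analyses:
#'   `social_NV` (channels responsive to both N and V), `fam1`,
#'   `nv_contrast` (N > V selectivity), `habituation`.
#' @export
roiRegistry <- function() {
  list(
    UK = list(
      social_NV   = list(HbO = c(9L, 15L, 16L, 18L), HbR = c(15L, 18L)),
      fam1        = list(HbO = c(4L, 7L), HbR = c(7L, 15L, 18L)),
      nv_contrast = list(HbO = c(4L, 13L, 14L, 15L, 16L),
                         HbR = c(4L, 7L, 9L, 13L, 14L, 15L, 16L, 17L, 18L)),
      habituation = list(HbO = c(4L, 7L), HbR = c(7L))
    ),
    GM = list(
      social_NV   = list(HbO = c(15L, 16L, 18L),
                         HbR = c(6L, 7L, 9L, 10L, 13L, 15L, 16L, 18L)),
      fam1        = list(HbO = c(1L, 4L, 7L, 13L), HbR = c(4L, 7L, 13L)),
      habituation = list(HbO = c(1L, 7L), HbR = c(4L, 7L, 13L))
    )
  )
}

#' Average the windowed mean response over an ROI
#'
#' @param responses data.frame from [meanResponse()] (channel, chromophore,
#'   condition, value) for one subject, or a long table with a subject
#'   column.
#' @param channels integer channel ids forming the ROI.
#' @param chromophore `"HbO"` or `"HbR"`.
#' @param condition condition label.
#' @return scalar (single subject) or named numeric per subject.
#' @export
roiMean <- function(responses, channels, chromophore, condition) {
  sel <- responses$chromophore == chromophore &
    responses$condition == condition & responses$channel %in% channels
  sub <- responses[sel, , drop = FALSE]
  missing <- setdiff(channels, unique(sub$channel))
  if (length(missing))
    stop("missing ROI channel(s): ", paste(missing, collapse = ", "))
  if ("subject" %in% names(sub)) {
    out <- tapply(sub$value, sub$subject, mean)
    setNames(as.numeric(out), names(out))
  } else mean(sub$value)
}

#' Compare ROI amplitudes or condition contrasts between sleep-stage groups
#'
#' Applies the 1.5 x IQR outlier rule within each sleep-stage group, then
#' runs the full two-group report (t-test, pooled Cohen's d, permutation p,
#' bootstrap CI). Inputs are per-subject ROI amplitudes, or per-subject
#' contrast values (e.g. N - V, Fam1 - Fam3) computed by the caller.
#'
#' @param qsValues,asValues per-subject values for the QS and AS groups.
#' @param variant t-test variant; pooled by default for ROI comparisons.
#' @param params a [statsParams()].
#' @param iqrFilterOn apply the outlier rule before testing.
#' @return one-row data.frame as [compareGroups()], comparing AS - QS
#'   (group A = AS, matching the report layout), plus nRemovedQS/AS.
#' @export
roiGroupComparison <- function(qsValues, asValues, variant = "pooled",
                               params = statsParams(), iqrFilterOn = TRUE) {
  if (iqrFilterOn) {
    fq <- iqrFilter(qsValues, params$iqrMultiplier)
    fa <- iqrFilter(asValues, params$iqrMultiplier)
    qs <- fq$retained; as_ <- fa$retained
  } else {
    qs <- qsValues; as_ <- asValues
  }
  if (length(qs) < 2 || length(as_) < 2)
    stop("fewer than 2 subjects per group after outlier filtering")
  out <- compareGroups(as_, qs, variant, params)
  out$nRemovedQS <- length(qsValues) - length(qs)
  out$nRemovedAS <- length(asValues) - length(as_)
  out
}

#' Channel-wise activation and contrast analysis for one sleep-stage group
#'
#' Stage 1: per chromophore, 18 two-tailed one-sample t-tests of the
#' windowed mean response against zero (the pre-stimulus baseline), with
#' Benjamini-Hochberg correction across the 18 channels. Stage 2: channels
#' significant against baseline are tested for the condition contrast with
#' two-tailed paired t-tests, BH-corrected over the stage-1-significant set
#' (configurable to the full 18-channel family). Activation calls treat an
#' HbO increase and/or HbR decrease as cortical activation; channels where
#' both chromophores move significantly in the same direction are flagged
#' atypical and excluded from interpretation.
#'
#' @param responses matrix-like per-subject responses: a named list with
#'   one `[subject x 18]` matrix per chromophore for the tested condition.
#' @param contrastResponses optional same-shaped list for the comparison
#'   condition (enables stage 2).
#' @param params a [statsParams()].
#' @param contrastFamily `"significant"` (BH over stage-1-significant
#'   channels) or `"all"` (full 18-channel family).
#' @return list with `activation` (per chromophore: data.frame channel, t,
#'   p, pAdj, significant, direction), `contrast` (same layout, stage-2
#'   channels only), and `calls` (data.frame channel, chromophore,
#'   direction, activated, atypical).
#' @export
channelwiseAnalysis <- function(responses, contrastResponses = NULL,
                                params = statsParams(),
                                contrastFamily = c("significant", "all")) {
  contrastFamily <- match.arg(contrastFamily)
  chroms <- names(responses)
  if (any(vapply(responses, nrow, 1L) < 3))
    stop("need at least 3 subjects")
  activation <- list(); contrast <- list()
  for (cr in chroms) {
    m <- responses[[cr]]
    nCh <- ncol(m)
    tt <- apply(m, 2, function(col) {
      lt <- locationTest(col)
      c(lt$statistic, lt$pParametric)
    })
    adj <- bhFdr(tt[2, ], params$alpha)
    activation[[cr]] <- data.frame(
      channel = seq_len(nCh), t = tt[1, ], p = tt[2, ],
      pAdj = adj$adjusted, significant = adj$significant,
      direction = sign(tt[1, ]))
    if (!is.null(contrastResponses)) {
      sig <- which(adj$significant)
      if (length(sig)) {
        mc <- contrastResponses[[cr]]
        ttc <- vapply(sig, function(ch) {
          lt <- locationTest(m[, ch], mc[, ch], mode = "paired")
          c(lt$statistic, lt$pParametric)
        }, numeric(2))
        pAdjC <- if (contrastFamily == "significant")
          p.adjust(ttc[2, ], method = "BH")
        else {
          full <- rep(NA_real_, nCh); full[sig] <- ttc[2, ]
          p.adjust(full, method = "BH", n = nCh)[sig]
        }
        contrast[[cr]] <- data.frame(
          channel = sig, t = ttc[1, ], p = ttc[2, ], pAdj = pAdjC,
          significant = pAdjC < params$alpha, direction = sign(ttc[1, ]))
      } else {
        contrast[[cr]] <- data.frame(channel = integer(0), t = numeric(0),
                                     p = numeric(0), pAdj = numeric(0),
                                     significant = logical(0),
                                     direction = numeric(0))
      }
    }
  }
  calls <- .activationCalls(activation)
  list(activation = activation, contrast = contrast, calls = calls)
}

# canonical activation: HbO up and/or HbR down; same-direction significance
# in both chromophores is atypical.
.activationCalls <- function(activation) {
  nCh <- nrow(activation[[1]])
  hbo <- activation[["HbO"]]; hbr <- activation[["HbR"]]
  rows <- list()
  for (ch in seq_len(nCh)) {
    hboSig <- !is.null(hbo) && hbo$significant[ch]
    hbrSig <- !is.null(hbr) && hbr$significant[ch]
    atyp <- hboSig && hbrSig &&
      hbo$direction[ch] == hbr$direction[ch]
    if (hboSig) rows[[length(rows) + 1L]] <- data.frame(
      channel = ch, chromophore = "HbO", direction = hbo$direction[ch],
      activated = hbo$direction[ch] > 0 && !atyp, atypical = atyp)
    if (hbrSig) rows[[length(rows) + 1L]] <- data.frame(
      channel = ch, chromophore = "HbR", direction = hbr$direction[ch],
      activated = hbr$direction[ch] < 0 && !atyp, atypical = atyp)
  }
  if (!length(rows))
    return(data.frame(channel = integer(0), chromophore = character(0),
                      direction = numeric(0), activated = logical(0),
                      atypical = logical(0)))
  do.call(rbind, rows)
}

#' Data-quality comparison table between sleep-stage groups
#'
#' For stage-constant subjects only: compares the percentage of clean
#' (motion-free) data and the number of valid trials per condition between
#' the AS and QS groups, reporting group means (SD), Welch t, p, pooled
#' Cohen's d, the bootstrap CI for d and the permutation p — one row per
#' metric.
#'
#' @param metrics data.frame with columns subject, group (QS/AS),
#'   stageConstant, pctClean, and one `nValid_<condition>` column per
#'   condition.
#' @param params a [statsParams()].
#' @param variant t-test variant (Welch for data-quality comparisons).
#' @return data.frame, one row per metric, in the report column layout.
#' @export
dataQualityTable <- function(metrics, params = statsParams(),
                             variant = "welch") {
  keep <- metrics$stageConstant & metrics$group %in% c("QS", "AS")
  m <- metrics[keep, , drop = FALSE]
  if (!nrow(m) || length(unique(m$group)) < 2) stop("empty sleep-stage group")
  metricCols <- c("pctClean", grep("^nValid_", names(m), value = TRUE))
  rows <- lapply(metricCols, function(col) {
    a <- m[[col]][m$group == "AS"]; q <- m[[col]][m$group == "QS"]
    out <- compareGroups(a, q, variant, params)
    cbind(data.frame(metric = col, stringsAsFactors = FALSE), out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
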