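# End-to-end orchestration: simulate -> code sleep -> preprocess ->
# allocate -> analyse -> report.

#' Run the full sleep-stage analysis pipeline on a synthetic cohort
#'
#' Executes simulation, codability screening, preprocessing, sleep-stage
#' allocation, the data-quality comparison and the ROI-based and
#' channel-wise analyses, writing CSV/JSON reports and a run log (seeds,
#' exclusion ledger) when `outDir` is given. Deterministic for a fixed
#' `(config, seed)`.
#'
#' @param config cohort configuration for [generateCohort()], optionally
#'   with `cohortLabel` (UK/GM, selects the ROI registry entry), `window`
#'   (analysis window, s) and `stats` (a [statsParams()]).
#' @param seed master seed.
#' @param outDir optional output directory for reports.
#' @return list with cohort manifest, exclusion ledger, QC metrics,
#'   allocations, data-quality table, per-subject mean responses, ROI and
#'   channel-wise results.
#' @export
runPipeline <- function(config, seed = 1L, outDir = NULL) {
  stats <- config$stats %||% statsParams(seed = seed)
  window <- config$window %||% c(8, 16)
  cohortLabel <- config$cohortLabel %||% "UK"
  scheme <- config$scheme %||% codingScheme()

  cohort <- generateCohort(config, seed = seed)
  paradigm <- cohort$paradigm
  ledger <- list(total = length(cohort$subjects), codability = 0L,
                 datasetQuality = 0L, tooFewTrials = 0L, analysed = 0L)

  subjects <- list(); qcRows <- list(); respRows <- list()
  for (sub in cohort$subjects) {
    cod <- assessCodability(sub$sheet, scheme)
    if (!cod$include) { ledger$codability <- ledger$codability + 1L; next }
    pp <- tryCatch(preprocessRecording(sub$recording, paradigm),
                   nirsleep_subject_exclusion = function(e) e)
    if (inherits(pp, "condition")) {
      ledger$tooFewTrials <- ledger$tooFewTrials + 1L; next
    }
    if (!pp$qc$datasetOk) {
      ledger$datasetQuality <- ledger$datasetQuality + 1L; next
    }
    ledger$analysed <- ledger$analysed + 1L
    sub$preprocessed <- pp
    subjects[[sub$subjectId]] <- sub
    nv <- nValidTrials(pp$block)
    qcRow <- data.frame(subject = sub$subjectId, pctClean = pp$qc$pctClean,
                        nBadChannels = length(pp$qc$badChannels),
                        meanScore = cod$meanScore)
    for (cond in names(nv)) qcRow[[paste0("nValid_", cond)]] <- nv[[cond]]
    qcRows[[sub$subjectId]] <- qcRow
    mr <- meanResponse(pp$block, window)
    mr$subject <- sub$subjectId
    respRows[[sub$subjectId]] <- mr
  }
  if (!length(subjects)) stop("no subject survived screening")
  qcTable <- do.call(rbind, lapply(qcRows, function(r) {
    for (col in setdiff(unique(unlist(lapply(qcRows, names))), names(r)))
      r[[col]] <- NA
    r
  }))
  responses <- do.call(rbind, respRows)
  rownames(qcTable) <- rownames(responses) <- NULL

  validList <- lapply(subjects, function(s) s$preprocessed$valid)
  allocations <- buildAnalysisGroups(
    list(subjects = subjects, paradigm = paradigm), valid = validList)

  # data-quality comparison over stage-constant subjects
  alloc1 <- allocations[!duplicated(allocations$subject), ]
  stageOf <- setNames(alloc1$group, alloc1$subject)
  constOf <- setNames(alloc1$stageConstant, alloc1$subject)
  metrics <- qcTable
  metrics$group <- stageOf[metrics$subject]
  metrics$stageConstant <- constOf[metrics$subject]
  dqTable <- tryCatch(dataQualityTable(metrics, stats),
                      error = function(e) NULL)

  # ROI-based comparison per analysis/chromophore
  registry <- roiRegistry()[[cohortLabel]]
  roiResults <- list()
  analyses <- unique(allocations$analysis)
  for (an in analyses) {
    alloc <- allocations[allocations$analysis == an, ]
    spec <- switch(an,
      social = list(roi = "social_NV", condA = "N", condB = "V"),
      hand_fam1 = list(roi = "fam1", condA = "Fam1", condB = NULL),
      hand_habituation = list(roi = "habituation", condA = "Fam1",
                              condB = "Fam3"),
      hand_novelty = list(roi = "fam1", condA = "novel", condB = "Fam3"),
      NULL)
    if (is.null(spec) || !spec$roi %in% names(registry)) next
    for (cr in c("HbO", "HbR")) {
      chans <- registry[[spec$roi]][[cr]]
      vals <- function(grp) {
        ids <- alloc$subject[alloc$group == grp]
        v <- vapply(ids, function(id) {
          r <- responses[responses$subject == id, ]
          a <- roiMean(r, chans, cr, spec$condA)
          if (is.null(spec$condB)) a
          else a - roiMean(r, chans, cr, spec$condB)
        }, numeric(1))
        v[!is.na(v)]
      }
      qs <- tryCatch(vals("QS"), error = function(e) numeric(0))
      as_ <- tryCatch(vals("AS"), error = function(e) numeric(0))
      if (length(qs) >= 3 && length(as_) >= 3) {
        res <- roiGroupComparison(qs, as_, params = stats)
        res$analysis <- an; res$chromophore <- cr
        roiResults[[paste(an, cr, sep = "_")]] <- res
      }
    }
  }
  roiTable <- if (length(roiResults)) do.call(rbind, roiResults) else NULL

  # channel-wise analysis per stage group (primary condition per paradigm)
  channelwise <- list()
  primaryAn <- if (paradigm@name == "social_selectivity") "social" else "hand_fam1"
  primaryCond <- if (paradigm@name == "social_selectivity") "N" else "Fam1"
  contrastCond <- if (paradigm@name == "social_selectivity") "V" else "Fam3"
  alloc <- allocations[allocations$analysis == primaryAn, ]
  for (grp in c("QS", "AS")) {
    ids <- alloc$subject[alloc$group == grp]
    if (length(ids) < 3) next
    mats <- lapply(c("HbO", "HbR"), function(cr) {
      t(vapply(ids, function(id) {
        r <- responses[responses$subject == id &
                         responses$chromophore == cr &
                         responses$condition == primaryCond, ]
        r$value[order(r$channel)]
      }, numeric(18)))
    })
    names(mats) <- c("HbO", "HbR")
    cmats <- lapply(c("HbO", "HbR"), function(cr) {
      t(vapply(ids, function(id) {
        r <- responses[responses$subject == id &
                         responses$chromophore == cr &
                         responses$condition == contrastCond, ]
        r$value[order(r$channel)]
      }, numeric(18)))
    })
    names(cmats) <- c("HbO", "HbR")
    channelwise[[grp]] <- channelwiseAnalysis(mats, cmats, stats)
  }

  bundle <- list(manifest = cohort$manifest, ledger = ledger, qc = qcTable,
                 allocations = allocations, dataQuality = dqTable,
                 responses = responses, roi = roiTable,
                 channelwise = channelwise, seed = seed)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cohort$manifest, file.path(outDir, "manifest.csv"),
              row.names = FALSE)
    write.csv(qcTable, file.path(outDir, "qc.csv"), row.names = FALSE)
    write.csv(allocations, file.path(outDir, "allocations.csv"),
              row.names = FALSE)
    write.csv(responses, file.path(outDir, "mean_responses.csv"),
              row.names = FALSE)
    if (!is.null(dqTable))
      write.csv(dqTable, file.path(outDir, "data_quality.csv"),
                row.names = FALSE)
    if (!is.null(roiTable))
      write.csv(roiTable, file.path(outDir, "roi_results.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, paradigm = paradigm@name, exclusions = ledger,
           packageVersion = as.character(utils::packageVersion("nirsleep"))),
      file.path(outDir, "run_log.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  bundle
}
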