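# Plain-text interchange: BIDS-style event TSVs, coding-sheet CSVs,
# long-format intensity CSVs, cohort manifests and YAML configs.

#' Write a stimulus schedule as a BIDS-style events TSV
#' @param events event data.frame (onset, duration, condition, ...).
#' @param path output path.
#' @export
writeEventsTSV <- function(events, path) {
  out <- data.frame(onset = events$onset, duration = events$duration,
                    trial_type = events$condition)
  extra <- setdiff(names(events), c("onset", "duration", "condition"))
  for (col in extra) out[[col]] <- events[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#' @param path file path.
#' @return event data.frame with onset, duration, condition columns.
#' @export
readEventsTSV <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(x)[names(x) == "trial_type"] <- "condition"
  x
}

#' Write a coding sheet as CSV
#' @param sheet a [CodingSheet-class].
#' @param path output path.
#' @export
writeCodingSheetCSV <- function(sheet, path) {
  ep <- sheet@epochs
  out <- data.frame(epoch_index = seq_len(nrow(ep)),
                    epoch_start_s = ep$start, stage = ep$stage,
                    criteria_observed = ep$criteriaObserved,
                    score = ep$score)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a coding sheet CSV
#' @param path file path.
#' @param subjectId subject identifier.
#' @return A [CodingSheet-class].
#' @export
readCodingSheetCSV <- function(path, subjectId = basename(path)) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$criteria_observed[is.na(x$criteria_observed)] <- ""
  ep <- data.frame(start = x$epoch_start_s, stage = x$stage,
                   criteriaObserved = x$criteria_observed, score = x$score,
                   stringsAsFactors = FALSE)
  epl <- if (nrow(ep) > 1) ep$start[2] - ep$start[1] else 15
  new("CodingSheet", subjectId = subjectId, epochs = ep, epochLength = epl)
}

#' Write a recording as long-format CSV (time, channel, wavelength, intensity)
#'
#' @param recording a [RawRecording-class].
#' @param path output path.
#' @export
writeRecordingCSV <- function(recording, path) {
  d <- dim(recording@intensity)
  fs <- recording@layout@samplingRate
  wl <- recording@layout@wavelengths
  long <- expand.grid(time = (seq_len(d[3]) - 1) / fs,
                      channel = seq_len(d[1]), wavelength = wl)
  long <- long[order(long$channel, long$wavelength, long$time), ]
  long$intensity <- as.numeric(vapply(seq_len(d[1]), function(ch)
    c(recording@intensity[ch, 1, ], recording@intensity[ch, 2, ]),
    numeric(2 * d[3])))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Export a synthetic cohort to a directory of plain-text files
#'
#' Writes per-subject events TSVs, coding-sheet CSVs and (optionally) the
#' long-format intensity CSVs, plus `manifest.csv`.
#'
#' @param cohort a cohort from [generateCohort()].
#' @param dir output directory (created if needed).
#' @param writeIntensity also write the (large) intensity CSVs.
#' @return the directory, invisibly.
#' @export
exportCohort <- function(cohort, dir, writeIntensity = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in cohort$subjects) {
    writeEventsTSV(sub$schedule,
                   file.path(dir, paste0(sub$subjectId, "_events.tsv")))
    writeCodingSheetCSV(sub$sheet,
                        file.path(dir, paste0(sub$subjectId, "_coding.csv")))
    if (writeIntensity)
      writeRecordingCSV(sub$recording,
                        file.path(dir, paste0(sub$subjectId, "_intensity.csv")))
  }
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a pipeline/cohort configuration from YAML
#' @param path YAML file path.
#' @return configuration list.
#' @export
readConfigYAML <- function(path) yaml::read_yaml(path)
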