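# Behavioural sleep-stage coding: codability scoring, exclusion threshold,
# timeline derivation and inter-rater reliability.

#' Construct a behavioural coding scheme
#'
#' Each criterion carries a weight (percent of a total possible epoch score
#' of 100) and a stage applicability (QS, AS or both). Criteria that are
#' mutually exclusive between stages (eye movements: REM vs no-REM;
#' respiration: regular vs irregular) carry higher weights than behaviours
#' that can occur in both stages (startles, general body movements). The
#' default weight table is the package's own (the published supplementary
#' weights are not available) and is fully overridable.
#'
#' @param criteria data.frame with columns name, applicability
#'   (QS/AS/both) and weight; defaults to the package scheme.
#' @param epochLength epoch duration in seconds.
#' @param codabilityThreshold mean epoch score (percent) below which a
#'   recording is excluded (65 by default; exactly 65 is included).
#' @return A list of class `"CodingScheme"`.
#' @examples
#' codingScheme()
#' @export
codingScheme <- function(criteria = NULL, epochLength = 15,
                         codabilityThreshold = 65) {
  if (is.null(criteria)) {
    criteria <- data.frame(
      name = c("eye_movements", "respiration_pattern", "body_movements",
               "startles", "sucking"),
      applicability = "both",
      weight = c(35, 35, 15, 10, 5),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "applicability", "weight") %in% names(criteria)),
            all(criteria$weight > 0),
            all(criteria$applicability %in% c("QS", "AS", "both")))
  for (st in c("QS", "AS")) {
    w <- sum(criteria$weight[criteria$applicability %in% c(st, "both")])
    if (abs(w - 100) > 1e-9)
      stop("criterion weights applicable to ", st, " must sum to 100, got ", w)
  }
  structure(list(criteria = criteria, epochLength = epochLength,
                 codabilityThreshold = codabilityThreshold),
            class = "CodingScheme")
}

#' Read a coding scheme from YAML
#'
#' Expects top-level `epoch_length_s`, `codability_threshold_pct` and a
#' `criteria` list of (name, applicability, weight) entries; see
#' `system.file("extdata", "coding_scheme.yaml", package = "nirsleep")`.
#'
#' @param path YAML file path.
#' @return A [codingScheme()].
#' @export
codingSchemeFromYAML <- function(path) {
  y <- yaml::read_yaml(path)
  cr <- do.call(rbind, lapply(y$criteria, function(c)
    data.frame(name = c$name, applicability = c$applicability,
               weight = c$weight, stringsAsFactors = FALSE)))
  codingScheme(cr, epochLength = y$epoch_length_s %||% 15,
               codabilityThreshold = y$codability_threshold_pct %||% 65)
}

#' Score one 15-s epoch from the observed criteria
#'
#' Sums the weights of all criteria that could be reliably observed during
#' the epoch, yielding a codability score between 0 (nothing visible) and
#' 100 (all criteria observable).
#'
#' @param criteriaObserved character vector of observed criterion names.
#' @param scheme a [codingScheme()].
#' @param stage optional stage restricting which criteria are applicable.
#' @return Numeric score in \[0, 100\].
#' @examples
#' scoreEpoch(c("eye_movements", "respiration_pattern"), codingScheme())
#' @export
scoreEpoch <- function(criteriaObserved, scheme = codingScheme(), stage = NULL) {
  cr <- scheme$criteria
  if (!is.null(stage)) cr <- cr[cr$applicability %in% c(stage, "both"), ]
  unknown <- setdiff(criteriaObserved, cr$name)
  if (length(unknown))
    stop("unknown criterion name(s): ", paste(unknown, collapse = ", "))
  sum(cr$weight[cr$name %in% criteriaObserved])
}

#' Assess codability of a coding sheet and apply the exclusion rule
#'
#' A recording is excluded when the mean epoch score across all epochs is
#' strictly below the threshold (65 percent); a mean of exactly 65 is
#' included.
#'
#' @param sheet a [CodingSheet-class].
#' @param scheme a [codingScheme()] supplying the threshold.
#' @return list with `meanScore` and logical `include`.
#' @export
assessCodability <- function(sheet, scheme = codingScheme()) {
  stopifnot(is(sheet, "CodingSheet"))
  if (nrow(sheet@epochs) == 0L) stop("coding sheet has no epochs")
  m <- mean(sheet@epochs$score)
  list(meanScore = m, include = m >= scheme$codabilityThreshold)
}

#' Derive a sleep timeline from a coding sheet
#'
#' Merges consecutive same-stage epochs into intervals and records every
#' stage change as a transition.
#'
#' @param sheet a [CodingSheet-class].
#' @return A [SleepTimeline-class].
#' @export
deriveTimeline <- function(sheet) {
  stopifnot(is(sheet, "CodingSheet"))
  sleepTimeline(sheet@epochs$stage, epochLength = sheet@epochLength)
}

#' Intraclass correlation ICC(2,1): two-way random effects, absolute agreement
#'
#' Single-measure intraclass correlation from the two-way random-effects
#' ANOVA decomposition with absolute agreement,
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the subject, rater and
#' residual mean squares over \eqn{n} subjects and \eqn{k} raters.
#'
#' @param ratings numeric matrix `[subject x rater]` with no missing cells.
#' @return list with `icc`, the mean squares, and a `degenerate` flag set
#'   when both the between-subject and residual variances vanish.
#' @examples
#' m <- cbind(c(10, 50, 80, 30), c(12, 48, 85, 29))
#' iccAgreement(m)$icc
#' @export
iccAgreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("missing cells are not supported")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  degenerate <- abs(denom) < 1e-12
  icc <- if (degenerate) NA_real_ else (msr - mse) / denom
  list(icc = icc, msr = msr, msc = msc, mse = mse, degenerate = degenerate)
}
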