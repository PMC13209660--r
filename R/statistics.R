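# Statistics kernel: t-tests (samples or summary statistics), Cohen's d,
# IQR outlier filtering, Benjamini-Hochberg FDR, permutation tests and
# bootstrap confidence intervals.

#' Resampling and testing parameters
#'
#' @param alpha significance level.
#' @param nPermutations label permutations (exhaustive enumeration is used
#'   when the total number of arrangements does not exceed this).
#' @param nBootstrap bootstrap resamples.
#' @param ciLevel confidence level for bootstrap intervals.
#' @param iqrMultiplier fence multiplier for outlier filtering.
#' @param seed RNG seed used by the resampling procedures.
#' @return list of class `"StatsParams"`.
#' @export
statsParams <- function(alpha = 0.05, nPermutations = 5000,
                        nBootstrap = 5000, ciLevel = 0.95,
                        iqrMultiplier = 1.5, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, nPermutations >= 1, nBootstrap >= 1)
  structure(list(alpha = alpha, nPermutations = nPermutations,
                 nBootstrap = nBootstrap, ciLevel = ciLevel,
                 iqrMultiplier = iqrMultiplier, seed = as.integer(seed)),
            class = "StatsParams")
}

.summaryStats <- function(x) {
  if (is.list(x) && all(c("mean", "sd", "n") %in% names(x)))
    return(list(mean = x$mean, sd = x$sd, n = x$n))
  list(mean = mean(x), sd = sd(x), n = length(x))
}

#' Two-sample t-test from samples or summary statistics
#'
#' Welch variant: unpooled standard error with Welch-Satterthwaite degrees
#' of freedom. Pooled variant: pooled variance with `n1 + n2 - 2` degrees
#' of freedom. Accepts either raw samples or `list(mean=, sd=, n=)`
#' summaries, so printed group summaries can be re-analysed directly.
#'
#' @param a,b numeric samples, or summary lists with mean, sd, n.
#' @param variant `"welch"` or `"pooled"`.
#' @return one-row data.frame: statistic, df, pParametric, effectSizeD,
#'   n1, n2, variant (effect size is the pooled-SD Cohen's d).
#' @examples
#' twoSampleT(list(mean = 95.3, sd = 3.0, n = 18),
#'            list(mean = 99.9, sd = 0.3, n = 14))
#' @export
twoSampleT <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  sa <- .summaryStats(a); sb <- .summaryStats(b)
  if (sa$n < 2 || sb$n < 2) stop("need n >= 2 per group")
  if (sa$sd == 0 && sb$sd == 0 && sa$mean == sb$mean)
    stop("zero variance in both groups with equal means: t undefined")
  va <- sa$sd^2; vb <- sb$sd^2
  diff <- sa$mean - sb$mean
  if (variant == "welch") {
    se2 <- va / sa$n + vb / sb$n
    tstat <- diff / sqrt(se2)
    df <- se2^2 / ((va / sa$n)^2 / (sa$n - 1) + (vb / sb$n)^2 / (sb$n - 1))
  } else {
    sp2 <- ((sa$n - 1) * va + (sb$n - 1) * vb) / (sa$n + sb$n - 2)
    tstat <- diff / sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    df <- sa$n + sb$n - 2
  }
  p <- 2 * pt(-abs(tstat), df)
  data.frame(statistic = tstat, df = df, pParametric = p,
             effectSizeD = cohensD(sa, sb), n1 = sa$n, n2 = sb$n,
             variant = variant, stringsAsFactors = FALSE)
}

#' Pooled-SD Cohen's d
#'
#' `(mean_a - mean_b) / s_p` with the pooled SD weighting each group's
#' variance by `n - 1`.
#'
#' @inheritParams twoSampleT
#' @return numeric effect size.
#' @examples
#' cohensD(list(mean = 95.3, sd = 3.0, n = 18),
#'         list(mean = 99.9, sd = 0.3, n = 14))
#' @export
cohensD <- function(a, b) {
  sa <- .summaryStats(a); sb <- .summaryStats(b)
  sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / (sa$n + sb$n - 2)
  if (sp2 == 0) stop("zero pooled SD: d undefined")
  (sa$mean - sb$mean) / sqrt(sp2)
}

#' One-sample or paired t-test
#'
#' One-sample mode tests `mean(x)` against zero (block averages are
#' baseline-referenced, so zero is the resting baseline); paired mode tests
#' the mean of `x - y`.
#'
#' @param x numeric sample.
#' @param y second sample (paired mode).
#' @param mode `"one_sample"` or `"paired"`.
#' @return one-row data.frame: statistic, df, pParametric, effectSizeD
#'   (mean / SD), n, variant.
#' @export
locationTest <- function(x, y = NULL, mode = c("one_sample", "paired")) {
  mode <- match.arg(mode)
  d <- if (mode == "paired") {
    stopifnot(!is.null(y), length(x) == length(y))
    x - y
  } else x
  n <- length(d)
  if (n < 2) stop("need n >= 2")
  s <- sd(d)
  if (s == 0) stop("zero variance: t undefined")
  tstat <- mean(d) / (s / sqrt(n))
  data.frame(statistic = tstat, df = n - 1,
             pParametric = 2 * pt(-abs(tstat), n - 1),
             effectSizeD = mean(d) / s, n = n, variant = mode,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values (monotone-enforced, as in
#' `p.adjust(method = "BH")`); a test is significant when its adjusted p
#' falls below `alpha`.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param alpha significance level.
#' @return list with `adjusted` p-values and logical `significant`.
#' @examples
#' bhFdr(c(0.001, 0.01, 0.02, 0.5))
#' @export
bhFdr <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- p.adjust(p, method = "BH")
  list(adjusted = adj, significant = adj < alpha)
}

#' Filter extreme values by the k x IQR rule
#'
#' Drops values below `Q1 - k*IQR` or above `Q3 + k*IQR`, with quartiles by
#' linear interpolation between order statistics (R's default type-7
#' quantiles). Applied within each sleep-stage group separately by the
#' analysis layer.
#'
#' @param x numeric sample.
#' @param k IQR multiplier.
#' @return list with `retained` values, `dropped` values and `keep`
#'   logical index.
#' @examples
#' iqrFilter(c(1, 2, 3, 4, 100))$retained
#' @export
iqrFilter <- function(x, k = 1.5) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  keep <- x >= q[1] - k * iqr & x <= q[2] + k * iqr
  list(retained = x[keep], dropped = x[!keep], keep = keep)
}

#' Two-sided permutation test (label permutation or sign flipping)
#'
#' Two-sample mode permutes group labels; the p-value is the proportion of
#' arrangements (including the identity) whose statistic magnitude reaches
#' the observed one. Enumeration is exhaustive when the number of distinct
#' arrangements (`choose(n, n_a)`, or `2^n` sign patterns for the
#' one-sample analogue) does not exceed `nPermutations`; otherwise a seeded
#' Monte-Carlo sample of that size is used (observed arrangement included).
#'
#' @param a first sample.
#' @param b second sample; omit (NULL) for the one-sample sign-flip test of
#'   mean zero.
#' @param stat statistic: difference of means or the t statistic.
#' @param params a [statsParams()].
#' @return list with `p`, `observed` statistic and `exhaustive` flag.
#' @examples
#' permutationTest(c(0, 0), c(1, 1))$p   # 2/6
#' @export
permutationTest <- function(a, b = NULL, stat = c("mean_diff", "t"),
                            params = statsParams()) {
  stat <- match.arg(stat)
  if (is.null(b)) return(.signFlipTest(a, params))
  stopifnot(length(a) >= 1, length(b) >= 1)
  x <- c(a, b); na <- length(a); n <- length(x)
  statFun <- function(ia) {
    ga <- x[ia]; gb <- x[-ia]
    if (stat == "mean_diff") mean(ga) - mean(gb)
    else {
      va <- var(ga) / length(ga) + var(gb) / length(gb)
      if (va == 0) 0 else (mean(ga) - mean(gb)) / sqrt(va)
    }
  }
  obs <- statFun(seq_len(na))
  nArr <- choose(n, na)
  if (nArr <= params$nPermutations) {
    combs <- utils::combn(n, na)
    stats <- apply(combs, 2, statFun)
    p <- mean(abs(stats) >= abs(obs) - 1e-12)
    return(list(p = p, observed = obs, exhaustive = TRUE))
  }
  stats <- .withSeed(params$seed,
    vapply(seq_len(params$nPermutations - 1L), function(i)
      statFun(sample.int(n, na)), numeric(1)))
  p <- (1 + sum(abs(stats) >= abs(obs) - 1e-12)) / params$nPermutations
  list(p = p, observed = obs, exhaustive = FALSE)
}

.signFlipTest <- function(x, params = statsParams()) {
  n <- length(x)
  obs <- mean(x)
  if (2^n <= params$nPermutations) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats <- as.numeric(signs %*% x) / n
    p <- mean(abs(stats) >= abs(obs) - 1e-12)
    return(list(p = p, observed = obs, exhaustive = TRUE))
  }
  signs <- .withSeed(params$seed,
    matrix(sample(c(-1, 1), (params$nPermutations - 1L) * n,
                  replace = TRUE), ncol = n))
  stats <- as.numeric(signs %*% x) / n
  p <- (1 + sum(abs(stats) >= abs(obs) - 1e-12)) / params$nPermutations
  list(p = p, observed = obs, exhaustive = FALSE)
}

#' Percentile bootstrap confidence interval for Cohen's d
#'
#' Stratified resampling: each group is resampled with replacement within
#' itself; the pooled-SD d is recomputed per resample and the percentile
#' interval at `ciLevel` is returned. Degenerate resamples (zero pooled SD)
#' are dropped and redrawn implicitly by the percentile over valid
#' resamples. Seeded and fully deterministic.
#'
#' @param a,b numeric samples.
#' @param params a [statsParams()].
#' @return numeric `c(low, high)`.
#' @export
bootstrapDCI <- function(a, b, params = statsParams()) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  B <- params$nBootstrap
  na <- length(a); nb <- length(b)
  idx <- .withSeed(params$seed, list(
    a = matrix(sample.int(na, na * B, replace = TRUE), nrow = na),
    b = matrix(sample.int(nb, nb * B, replace = TRUE), nrow = nb)))
  ia <- idx$a; ib <- idx$b
  ma <- matrix(a[ia], nrow = na); mb <- matrix(b[ib], nrow = nb)
  meanA <- colMeans(ma); meanB <- colMeans(mb)
  varA <- (colMeans(ma^2) - meanA^2) * na / (na - 1)
  varB <- (colMeans(mb^2) - meanB^2) * nb / (nb - 1)
  sp2 <- ((na - 1) * varA + (nb - 1) * varB) / (na + nb - 2)
  ok <- sp2 > 0
  d <- (meanA[ok] - meanB[ok]) / sqrt(sp2[ok])
  alpha <- 1 - params$ciLevel
  as.numeric(quantile(d, c(alpha / 2, 1 - alpha / 2), names = FALSE))
}

#' Full two-group comparison report
#'
#' Combines the parametric t-test (Welch or pooled), pooled Cohen's d, a
#' permutation p-value and the bootstrap CI for d into one row matching the
#' data-quality/ROI report layout. Shapiro-Wilk normality p-values per
#' group are computed and attached for screening but never gate the test.
#'
#' @param a,b numeric samples.
#' @param variant t-test variant.
#' @param params a [statsParams()].
#' @return one-row data.frame: meanA, sdA, nA, meanB, sdB, nB, statistic,
#'   df, pParametric, effectSizeD, dCiLow, dCiHigh, pPermutation, variant,
#'   shapiroA, shapiroB.
#' @export
compareGroups <- function(a, b, variant = c("welch", "pooled"),
                          params = statsParams()) {
  variant <- match.arg(variant)
  tt <- twoSampleT(a, b, variant)
  perm <- permutationTest(a, b, "mean_diff", params)
  ci <- bootstrapDCI(a, b, params)
  shap <- function(x) if (length(x) >= 3 && length(x) <= 5000 && sd(x) > 0)
    stats::shapiro.test(x)$p.value else NA_real_
  data.frame(meanA = mean(a), sdA = sd(a), nA = length(a),
             meanB = mean(b), sdB = sd(b), nB = length(b),
             statistic = tt$statistic, df = tt$df,
             pParametric = tt$pParametric, effectSizeD = tt$effectSizeD,
             dCiLow = ci[1], dCiHigh = ci[2], pPermutation = perm$p,
             variant = variant, shapiroA = shap(a), shapiroB = shap(b),
             stringsAsFactors = FALSE)
}
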