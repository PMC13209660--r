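# Preprocessing chain: channel QC (SCI/PSP), intensity -> optical density,
# motion detection/rejection/correction, low-pass filtering, modified
# Beer-Lambert conversion, and trial-locked block averaging.

#' @importFrom signal butter filtfilt
NULL

#' Channel quality-control parameters
#'
#' @param cardiacBand infant cardiac band in Hz used for SCI/PSP.
#' @param sciThreshold scalp coupling index threshold.
#' @param pspThreshold peak spectral power threshold (normalised power;
#'   see the vignette for the unit convention).
#' @param maxBadChannelFraction datasets with a larger fraction of
#'   low-quality channels are excluded.
#' @param windowLength length (s) of the non-overlapping windows over which
#'   SCI/PSP are computed; the per-channel value is the median across
#'   windows, making the metrics robust to brief motion episodes.
#' @return list of class `"QCParams"`.
#' @export
qcParams <- function(cardiacBand = c(1.5, 3.5), sciThreshold = 0.7,
                     pspThreshold = 0.1, maxBadChannelFraction = 0.40,
                     windowLength = 30) {
  stopifnot(sciThreshold > 0, sciThreshold <= 1, cardiacBand[1] > 0,
            windowLength > 0)
  structure(list(cardiacBand = cardiacBand, sciThreshold = sciThreshold,
                 pspThreshold = pspThreshold,
                 maxBadChannelFraction = maxBadChannelFraction,
                 windowLength = windowLength),
            class = "QCParams")
}

#' Motion detection/correction parameters
#'
#' @param tMotion sliding-window length for excursion detection, seconds.
#' @param tMask dilation of motion flags on each side, seconds.
#' @param stdevThresh excursion threshold as a multiple of the channel SD.
#' @param ampThresh absolute excursion threshold, optical-density units.
#' @param splineP smoothing-spline parameter p (csaps convention; the
#'   roughness penalty is `(1-p)/p`).
#' @param waveletIQR IQR multiplier for wavelet-coefficient outliers.
#' @param maxMotionChannelFraction a trial is rejected when more than this
#'   fraction of channels is simultaneously flagged.
#' @return list of class `"MotionParams"`.
#' @export
motionParams <- function(tMotion = 1, tMask = 1, stdevThresh = 15,
                         ampThresh = 0.5, splineP = 0.99, waveletIQR = 0.8,
                         maxMotionChannelFraction = 0.50) {
  stopifnot(tMotion > 0, tMask > 0, stdevThresh > 0, ampThresh > 0,
            splineP > 0, splineP < 1, waveletIQR > 0)
  structure(list(tMotion = tMotion, tMask = tMask, stdevThresh = stdevThresh,
                 ampThresh = ampThresh, splineP = splineP,
                 waveletIQR = waveletIQR,
                 maxMotionChannelFraction = maxMotionChannelFraction),
            class = "MotionParams")
}

# Hemoglobin extinction coefficients, 1/(mM cm), standard tabulated values
# at the two system wavelengths (rows: 780, 850 nm; cols: HbO, HbR).
.DEFAULT_EXTINCTION <- matrix(c(0.7360, 1.1022,
                                1.0580, 0.6910),
                              nrow = 2, byrow = TRUE,
                              dimnames = list(c("780", "850"),
                                              c("HbO", "HbR")))

#' Chromophore conversion parameters
#'
#' Differential pathlength factors are mapped 5.22 to 780 nm and 4.23 to
#' 850 nm (DPF decreases with wavelength); both the mapping and the
#' extinction table are configurable.
#'
#' @param lowpass low-pass cutoff frequency, Hz.
#' @param dpf differential pathlength factors per wavelength.
#' @param separation source-detector separation, cm.
#' @param extinction 2x2 extinction matrix (wavelength x chromophore),
#'   1/(mM cm); must be invertible.
#' @return list of class `"ConversionParams"`.
#' @export
conversionParams <- function(lowpass = 0.6, dpf = c(5.22, 4.23),
                             separation = 2,
                             extinction = .DEFAULT_EXTINCTION) {
  if (abs(det(extinction)) < 1e-12) stop("extinction matrix is singular")
  structure(list(lowpass = lowpass, dpf = dpf, separation = separation,
                 extinction = extinction),
            class = "ConversionParams")
}

# Zero-phase band-pass to the cardiac band (demeaned, reflect-padded to
# suppress filtfilt edge transients).
.cardiacBandpass <- function(x, fs, band) {
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  n <- length(x)
  np <- min(n - 1L, 100L)
  xp <- c(rev(x[seq_len(np)]), x, rev(x)[seq_len(np)]) - mean(x)
  y <- signal::filtfilt(bf, xp)
  y[(np + 1L):(np + n)]
}

# split 1..n into non-overlapping windows of `w` samples (last partial
# window merged into the previous one)
.qcWindows <- function(n, w) {
  if (w >= n) return(list(seq_len(n)))
  starts <- seq(1L, n - w + 1L, by = w)
  lapply(seq_along(starts), function(i) {
    if (i == length(starts)) starts[i]:n else starts[i]:(starts[i] + w - 1L)
  })
}

# per-channel QC metric: median across windows of `fun(bandpassed a, b)`
.windowedCardiacMetric <- function(x, fs, qc, fun) {
  nC <- dim(x)[1]; n <- dim(x)[3]
  wins <- .qcWindows(n, round(qc$windowLength * fs))
  vapply(seq_len(nC), function(ch) {
    a <- as.numeric(x[ch, 1, ]); b <- as.numeric(x[ch, 2, ])
    if (sd(a) == 0 || sd(b) == 0) return(0)
    fa <- .cardiacBandpass(a / mean(a), fs, qc$cardiacBand)
    fb <- .cardiacBandpass(b / mean(b), fs, qc$cardiacBand)
    vals <- vapply(wins, function(idx) fun(fa[idx], fb[idx]), numeric(1))
    median(vals)
  }, numeric(1))
}

#' Scalp coupling index per channel
#'
#' Correlation between the two wavelengths' signals after zero-phase
#' band-pass filtering to the infant cardiac band, computed over
#' non-overlapping windows (`windowLength` seconds) and summarised as the
#' per-channel median, so brief motion episodes do not dominate the
#' metric. A well-coupled optode pair shares the cardiac pulsation across
#' wavelengths, driving the correlation toward 1. Constant (zero-variance)
#' channels get SCI 0.
#'
#' @param recording a [RawRecording-class] or a `[channel x 2 x time]`
#'   intensity array.
#' @param qc a [qcParams()].
#' @param fs sampling rate, needed only when `recording` is a bare array.
#' @return numeric vector of per-channel SCI values in \[-1, 1\].
#' @export
scalpCouplingIndex <- function(recording, qc = qcParams(), fs = NULL) {
  x <- if (is(recording, "RawRecording")) recording@intensity else recording
  if (is(recording, "RawRecording")) fs <- recording@layout@samplingRate
  .windowedCardiacMetric(x, fs, qc, function(fa, fb) {
    if (sd(fa) == 0 || sd(fb) == 0) 0 else stats::cor(fa, fb)
  })
}

#' Peak spectral power per channel
#'
#' Within each QC window the two wavelengths' cardiac-band signals are
#' standardised, averaged, Hann-windowed and Fourier transformed; the
#' window's PSP is the largest value of the power spectrum normalised to
#' unit total power, and the channel value is the median across windows. A
#' shared cardiac tone concentrates power in one bin (PSP near 1);
#' broadband independent noise spreads it (PSP near 1/nbins).
#'
#' @inheritParams scalpCouplingIndex
#' @return numeric vector of per-channel PSP values in \[0, 1\].
#' @export
peakSpectralPower <- function(recording, qc = qcParams(), fs = NULL) {
  x <- if (is(recording, "RawRecording")) recording@intensity else recording
  if (is(recording, "RawRecording")) fs <- recording@layout@samplingRate
  .windowedCardiacMetric(x, fs, qc, function(fa, fb) {
    if (sd(fa) == 0 || sd(fb) == 0) return(0)
    s <- (fa / sd(fa) + fb / sd(fb)) / 2
    n <- length(s)
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))   # Hann window
    p <- Mod(stats::fft(s * w))^2
    p <- p[2:floor(n / 2)]                                # drop DC, mirror
    if (sum(p) == 0) return(0)
    max(p) / sum(p)
  })
}

#' Dataset-level channel quality decision
#'
#' A channel is low quality when its SCI falls below the SCI threshold or
#' its PSP below the PSP threshold; the dataset is excluded when more than
#' 40 percent of channels are low quality.
#'
#' @param sci,psp per-channel values from [scalpCouplingIndex()] and
#'   [peakSpectralPower()].
#' @param qc a [qcParams()].
#' @return list with `badChannels` (integer indices) and `datasetOk`.
#' @export
assessDatasetQuality <- function(sci, psp, qc = qcParams()) {
  stopifnot(length(sci) == length(psp))
  bad <- which(sci < qc$sciThreshold | psp < qc$pspThreshold)
  list(badChannels = bad,
       datasetOk = length(bad) / length(sci) <= qc$maxBadChannelFraction)
}

#' Convert intensity to optical density
#'
#' \eqn{\Delta OD(t) = -\ln(I(t)/\bar I)} per channel and wavelength, so a
#' constant signal maps to zero and rescaling the intensity leaves the OD
#' unchanged.
#'
#' @param recording a [RawRecording-class] or `[channel x 2 x time]` array.
#' @return numeric array of the same dimensions.
#' @export
intensityToOD <- function(recording) {
  x <- if (is(recording, "RawRecording")) recording@intensity else recording
  if (any(x <= 0)) stop("intensity must be strictly positive")
  d <- dim(x)
  od <- x
  for (ch in seq_len(d[1])) for (w in 1:2) {
    v <- x[ch, w, ]
    od[ch, w, ] <- -log(v / mean(v))
  }
  od
}

# Running max-min excursion over windows of `w` samples (right-aligned
# windows starting at each sample).
.runningExcursion <- function(x, w) {
  n <- length(x)
  if (w >= n) return(rep(max(x) - min(x), n))
  emb <- stats::embed(x, w)            # rows: windows ending at w..n
  exc <- apply(emb, 1, max) - apply(emb, 1, min)
  # window starting at i covers i..i+w-1 -> embed row i
  c(exc, rep(exc[length(exc)], w - 1))
}

#' Detect motion artifacts by channel
#'
#' Within sliding windows of `tMotion` seconds, a channel-time is flagged
#' when the OD excursion (max minus min over the window, either wavelength)
#' exceeds `stdevThresh` times the channel's whole-record SD or exceeds
#' `ampThresh` (OD units). Flags are dilated by `tMask` seconds on each
#' side.
#'
#' @param od optical-density array `[channel x 2 x time]`.
#' @param mp a [motionParams()].
#' @param fs sampling rate, Hz.
#' @return logical matrix `[channel x time]`.
#' @export
detectMotionByChannel <- function(od, mp = motionParams(), fs = 10) {
  d <- dim(od)
  w <- max(2L, round(mp$tMotion * fs))
  maskLen <- round(mp$tMask * fs)
  mask <- matrix(FALSE, d[1], d[3])
  for (ch in seq_len(d[1])) {
    flag <- rep(FALSE, d[3])
    for (wl in 1:2) {
      x <- as.numeric(od[ch, wl, ])
      sdc <- sd(x)
      exc <- .runningExcursion(x, w)
      hit <- exc > mp$stdevThresh * sdc | exc > mp$ampThresh
      # a hit window flags all samples it covers
      idx <- which(hit)
      if (length(idx)) {
        flagw <- rep(FALSE, d[3])
        for (i in idx) flagw[i:min(d[3], i + w - 1L)] <- TRUE
        flag <- flag | flagw
      }
    }
    if (any(flag)) {
      idx <- which(flag)
      lo <- pmax(1L, idx - maskLen); hi <- pmin(d[3], idx + maskLen)
      dil <- rep(FALSE, d[3])
      for (j in seq_along(idx)) dil[lo[j]:hi[j]] <- TRUE
      flag <- dil
    }
    mask[ch, ] <- flag
  }
  mask
}

#' Reject trials contaminated by widespread motion
#'
#' A trial is invalid when, at any time inside its peristimulus
#' (block-average) window, more than half of the channels are
#' simultaneously flagged.
#'
#' @param mask logical `[channel x time]` from [detectMotionByChannel()].
#' @param events event data.frame (onset, duration).
#' @param paradigm a [ParadigmSpec-class] supplying the window (tRange).
#' @param mp a [motionParams()].
#' @param fs sampling rate, Hz.
#' @return logical vector, one validity flag per trial.
#' @export
rejectTrials <- function(mask, events, paradigm, mp = motionParams(),
                         fs = 10) {
  nT <- ncol(mask); nC <- nrow(mask)
  frac <- colSums(mask) / nC
  vapply(seq_len(nrow(events)), function(k) {
    i0 <- max(1L, round((events$onset[k] + paradigm@blockAverageRange[1]) * fs) + 1L)
    i1 <- min(nT, round((events$onset[k] + paradigm@blockAverageRange[2]) * fs))
    !any(frac[i0:i1] > mp$maxMotionChannelFraction)
  }, logical(1))
}

# ---- Haar DWT (periodised) ----------------------------------------------
# Small self-contained discrete wavelet transform used by the IQR-based
# motion correction; no wavelet package is required.
.haarForward <- function(x) {
  n <- length(x)
  J <- floor(log2(n))
  stopifnot(2^J == n)
  details <- vector("list", J)
  a <- x
  for (j in seq_len(J)) {
    even <- a[seq(2, length(a), 2)]; odd <- a[seq(1, length(a), 2)]
    details[[j]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(approx = a, details = details)
}

.haarInverse <- function(dec) {
  a <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    d <- dec$details[[j]]
    odd <- (a + d) / sqrt(2); even <- (a - d) / sqrt(2)
    out <- numeric(2 * length(a))
    out[seq(1, length(out), 2)] <- odd
    out[seq(2, length(out), 2)] <- even
    a <- out
  }
  a
}

# IQR-thresholded wavelet denoising of one series: detail coefficients
# outside [Q1 - k*IQR, Q3 + k*IQR] (per level) are set to zero.
.waveletIQRCorrect <- function(x, k) {
  n <- length(x)
  J <- floor(log2(n))
  npad <- 2^ceiling(log2(n))
  xp <- c(x, rev(x)[seq_len(npad - n)])       # symmetric pad to 2^J
  dec <- .haarForward(xp)
  for (j in seq_along(dec$details)) {
    d <- dec$details[[j]]
    if (length(d) < 4) next
    q <- quantile(d, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    out <- d < q[1] - k * iqr | d > q[2] + k * iqr
    d[out] <- 0
    dec$details[[j]] <- d
  }
  .haarInverse(dec)[seq_len(n)]
}

#' Correct motion artifacts by spline interpolation and wavelet filtering
#'
#' Flagged segments are fitted with a smoothing spline (parameter
#' `splineP`, csaps convention) and the fit is subtracted; each corrected
#' segment is re-anchored to the preceding clean sample and the data after
#' the segment are shifted to remove residual baseline steps. Channels that
#' carried motion flags are then passed through a per-level IQR-thresholded
#' discrete (Haar) wavelet filter (`waveletIQR` multiplier); channels
#' without flags are left untouched so that clean hemodynamics are never
#' distorted. Output length always equals input length.
#'
#' @param od optical-density array `[channel x 2 x time]`.
#' @param mask logical `[channel x time]` from [detectMotionByChannel()].
#' @param mp a [motionParams()].
#' @param fs sampling rate, Hz.
#' @return corrected OD array, same dimensions.
#' @export
correctMotion <- function(od, mask, mp = motionParams(), fs = 10) {
  d <- dim(od)
  out <- od
  lambda0 <- (1 - mp$splineP) / mp$splineP   # csaps roughness penalty
  for (ch in seq_len(d[1])) {
    if (!any(mask[ch, ])) next
    runs <- rle(mask[ch, ])
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    for (wl in 1:2) {
      x <- as.numeric(out[ch, wl, ])
      for (r in which(runs$values)) {
        i0 <- starts[r]; i1 <- ends[r]
        seg <- x[i0:i1]
        if (length(seg) < 4L) next                   # too short to fit
        tseg <- seq_along(seg)
        # smooth.spline standardises x to [0,1]; rescale the csaps penalty
        # by L^3 so splineP keeps its near-interpolating meaning
        lambda <- lambda0 / length(seg)^3
        fit <- tryCatch(
          stats::predict(stats::smooth.spline(tseg, seg, lambda = lambda,
                                              all.knots = TRUE),
                         tseg)$y,
          error = function(e) seg)
        resid <- seg - fit
        anchor <- if (i0 > 1L) x[i0 - 1L] else if (i1 < d[3]) x[i1 + 1L] else seg[1]
        corrected <- resid + anchor
        x[i0:i1] <- corrected
        if (i1 < d[3]) {                             # remove residual step
          offset <- x[i1 + 1L] - corrected[length(corrected)]
          x[(i1 + 1L):d[3]] <- x[(i1 + 1L):d[3]] - offset
        }
      }
      x <- .waveletIQRCorrect(x, mp$waveletIQR)
      out[ch, wl, ] <- x
    }
  }
  out
}

#' Zero-phase low-pass filter
#'
#' 5th-order Butterworth applied forward and backward (zero phase); the
#' passband gain is 1, so DC offsets are preserved exactly.
#'
#' @param od optical-density array `[channel x 2 x time]` (or a vector).
#' @param cp a [conversionParams()] supplying the cutoff.
#' @param fs sampling rate, Hz.
#' @return filtered data, same shape.
#' @export
lowpassFilter <- function(od, cp = conversionParams(), fs = 10) {
  bf <- signal::butter(5, cp$lowpass / (fs / 2), type = "low")
  # reflective padding + mean removal suppress filtfilt edge transients
  run <- function(x) {
    n <- length(x)
    np <- min(n - 1L, 200L)
    m <- mean(x)
    xp <- c(rev(x[seq_len(np)]), x, rev(x)[seq_len(np)]) - m
    y <- signal::filtfilt(bf, xp)
    y[(np + 1L):(np + n)] + m
  }
  if (is.null(dim(od))) return(run(od))
  d <- dim(od)
  out <- od
  for (ch in seq_len(d[1])) for (wl in 1:2)
    out[ch, wl, ] <- run(as.numeric(od[ch, wl, ]))
  out
}

#' Convert optical density to chromophore concentrations (modified
#' Beer-Lambert law)
#'
#' Solves, per channel and time point, the 2x2 system
#' \deqn{\Delta OD(\lambda) = [\varepsilon_{HbO}(\lambda)\Delta HbO +
#'   \varepsilon_{HbR}(\lambda)\Delta HbR]\, d\, DPF(\lambda)}
#' for \eqn{\Delta HbO} and \eqn{\Delta HbR} in micromolar.
#'
#' @param od optical-density array `[channel x 2 x time]`.
#' @param cp a [conversionParams()].
#' @return array `[channel x chromophore x time]`, micromolar; chromophore
#'   order HbO, HbR.
#' @export
odToConcentration <- function(od, cp = conversionParams()) {
  E <- cp$extinction * cp$separation * cp$dpf   # row-scaled by DPF
  Einv <- solve(E)
  d <- dim(od)
  conc <- array(0, dim = c(d[1], 2L, d[3]),
                dimnames = list(NULL, c("HbO", "HbR"), NULL))
  for (ch in seq_len(d[1])) {
    odm <- rbind(od[ch, 1, ], od[ch, 2, ])      # 2 x time
    cc <- Einv %*% odm                          # mM
    conc[ch, 1, ] <- cc[1, ] * 1000             # -> uM
    conc[ch, 2, ] <- cc[2, ] * 1000
  }
  conc
}

#' Trial-locked block average with detrending and baseline referencing
#'
#' The concentration series is first linearly detrended per channel and
#' chromophore (a line fitted to the whole recording, so slow drift is
#' removed without biasing the unimodal trial response). For each condition
#' with at least three valid trials, each valid trial's segment over the
#' paradigm's peristimulus window (tRange) is extracted, the mean of the
#' pre-stimulus baseline (-4 to 0 s) subtracted, and the segments averaged.
#' Conditions with fewer than three valid trials are dropped; if a required
#' condition is dropped the subject-exclusion error
#' (condition class `"nirsleep_subject_exclusion"`) is raised.
#'
#' @param conc concentration array `[channel x chromophore x time]`.
#' @param events event data.frame (onset, duration, condition).
#' @param valid logical validity flag per trial (from [rejectTrials()]).
#' @param paradigm a [ParadigmSpec-class].
#' @param fs sampling rate, Hz.
#' @param baselineWindow window (s, relative to onset) averaged as the
#'   pre-stimulus reference.
#' @param requiredConditions conditions whose loss excludes the subject;
#'   defaults to the paradigm's required set. Use `character(0)` to never
#'   raise.
#' @return A [BlockAverage-class].
#' @export
blockAverage <- function(conc, events, valid, paradigm, fs = 10,
                         baselineWindow = c(-4, 0),
                         requiredConditions = NULL) {
  if (is.null(requiredConditions))
    requiredConditions <- paradigm@requiredConditions
  rng <- paradigm@blockAverageRange
  relIdx <- seq(round(rng[1] * fs), round(rng[2] * fs))
  timeAxis <- relIdx / fs
  nT <- dim(conc)[3]
  base <- timeAxis >= baselineWindow[1] & timeAxis <= baselineWindow[2]

  # linear detrend of the continuous series per channel/chromophore
  Xfull <- cbind(1, seq_len(nT))
  qrX <- qr(Xfull)
  for (ch in seq_len(dim(conc)[1])) for (cr in 1:2) {
    y <- as.numeric(conc[ch, cr, ])
    conc[ch, cr, ] <- y - Xfull %*% qr.coef(qrX, y)
  }

  conds <- unique(events$condition)
  traces <- list(); nvalid <- integer(0); vidx <- list()
  for (cond in conds) {
    trialIdx <- which(events$condition == cond & valid)
    segs <- list()
    kept <- integer(0)
    for (k in trialIdx) {
      i0 <- round(events$onset[k] * fs)
      idx <- i0 + relIdx + 1L
      if (idx[1] < 1L || idx[length(idx)] > nT) next
      seg <- conc[, , idx, drop = FALSE]
      # subtract pre-stimulus baseline per channel/chromophore
      for (ch in seq_len(dim(seg)[1])) for (cr in 1:2) {
        y <- as.numeric(seg[ch, cr, ])
        seg[ch, cr, ] <- y - mean(y[base])
      }
      segs[[length(segs) + 1L]] <- seg
      kept <- c(kept, k)
    }
    if (length(segs) >= 3L) {
      acc <- segs[[1]]
      if (length(segs) > 1) for (s in segs[-1]) acc <- acc + s
      avg <- acc / length(segs)
      dimnames(avg) <- list(NULL, c("HbO", "HbR"), NULL)
      traces[[cond]] <- avg
      nvalid[cond] <- length(segs)
      vidx[[cond]] <- kept
    }
  }
  missing <- setdiff(requiredConditions, names(traces))
  if (length(missing)) {
    cond <- structure(class = c("nirsleep_subject_exclusion", "error",
                                "condition"),
                      list(message = paste0(
                        "fewer than 3 valid trials for required condition(s): ",
                        paste(missing, collapse = ", ")), call = NULL))
    stop(cond)
  }
  new("BlockAverage", traces = traces, timeAxis = timeAxis,
      nValidTrials = nvalid, validTrialIndices = vidx,
      paradigm = paradigm@name)
}

#' Windowed mean response per channel, chromophore and condition
#'
#' Time-mean of the block-average trace over the analysis window. The
#' default 8-16 s post-onset window brackets the HRF peak of an 8-s trial;
#' it is configurable per cohort and chromophore.
#'
#' @param block a [BlockAverage-class].
#' @param window analysis window in seconds, within the paradigm tRange.
#' @return data.frame with channel, chromophore, condition, value columns.
#' @export
meanResponse <- function(block, window = c(8, 16)) {
  sel <- block@timeAxis >= window[1] & block@timeAxis <= window[2]
  if (!any(sel)) stop("empty analysis window")
  rows <- list()
  for (cond in names(block@traces)) {
    tr <- block@traces[[cond]]
    for (cr in 1:2) {
      vals <- apply(tr[, cr, sel, drop = FALSE], 1, mean)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = seq_along(vals), chromophore = c("HbO", "HbR")[cr],
        condition = cond, value = vals, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentage of clean (motion-free) data
#'
#' `100 * (unflagged channel-samples / total channel-samples)` for one
#' recording's motion mask.
#'
#' @param mask logical `[channel x time]` from [detectMotionByChannel()].
#' @return percentage in \[0, 100\].
#' @export
percentCleanData <- function(mask) 100 * (1 - mean(mask))

#' Run the full preprocessing chain on one recording
#'
#' intensity -> QC (SCI/PSP, dataset exclusion) -> optical density ->
#' motion detection -> trial rejection -> motion correction (spline +
#' wavelet) -> low-pass -> modified Beer-Lambert -> block average.
#'
#' @param recording a [RawRecording-class].
#' @param paradigm a [ParadigmSpec-class].
#' @param qc,mp,cp parameter objects.
#' @param correctMotionOn apply spline/wavelet correction.
#' @param requiredConditions forwarded to [blockAverage()].
#' @return list with `block` ([BlockAverage-class]), `qc` (SCI/PSP,
#'   badChannels, datasetOk, pctClean), `valid` (per-trial flags),
#'   `mask`, `meanResponse` (default-window table).
#' @export
preprocessRecording <- function(recording, paradigm, qc = qcParams(),
                                mp = motionParams(), cp = conversionParams(),
                                correctMotionOn = TRUE,
                                requiredConditions = NULL) {
  fs <- recording@layout@samplingRate
  sci <- scalpCouplingIndex(recording, qc)
  psp <- peakSpectralPower(recording, qc)
  quality <- assessDatasetQuality(sci, psp, qc)
  od <- intensityToOD(recording)
  mask <- detectMotionByChannel(od, mp, fs)
  valid <- rejectTrials(mask, recording@events, paradigm, mp, fs)
  if (correctMotionOn) od <- correctMotion(od, mask, mp, fs)
  od <- lowpassFilter(od, cp, fs)
  conc <- odToConcentration(od, cp)
  block <- blockAverage(conc, recording@events, valid, paradigm, fs,
                        requiredConditions = requiredConditions)
  list(block = block,
       qc = list(sci = sci, psp = psp, badChannels = quality$badChannels,
                 datasetOk = quality$datasetOk,
                 pctClean = percentCleanData(mask)),
       valid = valid, mask = mask,
       meanResponse = meanResponse(block))
}
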