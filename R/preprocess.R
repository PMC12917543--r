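#' @include AllClasses.R
NULL

#' Condition a raw recording into analysis-ready trials
#'
#' Reproduces the standard resting-state conditioning chain: first-order
#' Butterworth band-pass 1-70 Hz (applied forward-backward for zero phase),
#' DFT notch of 50 Hz line noise and its harmonics at 100 and 150 Hz
#' (least-squares sine/cosine removal over the whole recording, at the raw
#' rate, before decimation), integer-factor decimation to 150 Hz behind a
#' zero-phase anti-alias guard (order-4 Butterworth at 0.8 x the new Nyquist,
#' 8th-order effective magnitude response), segmentation into contiguous
#' non-overlapping 10-s trials (remainder discarded), per-trial demeaning and
#' common average re-referencing.
#'
#' @param sensorData numeric matrix (channels x samples) in microvolts, or a
#'   \linkS4class{SubjectRecord}.
#' @param rawRate raw sampling rate, Hz; must be an integer multiple of 150.
#'   Taken from the record when \code{sensorData} is a
#'   \linkS4class{SubjectRecord}.
#' @param labels channel labels; taken from the record's layout when absent.
#' @param trialLength trial length in seconds (default 10).
#' @return a \linkS4class{TrialSet} at 150 Hz under the common average
#'   reference. A recording shorter than one trial yields an empty TrialSet
#'   with a warning.
#' @export
preprocessRecording <- function(sensorData, rawRate = NULL, labels = NULL,
                                trialLength = 10) {
  if (is(sensorData, "SubjectRecord")) {
    if (is.null(rawRate)) rawRate <- sensorData@samplingRate
    if (is.null(labels)) labels <- sensorData@layout@labels
    sensorData <- sensorData@sensorData
  }
  if (is.null(rawRate)) stop("rawRate is required for matrix input")
  if (rawRate %% 150 != 0) stop("raw sampling rate must be an integer multiple of 150 Hz")
  nCh <- nrow(sensorData)
  if (is.null(labels)) labels <- sprintf("CH%03d", seq_len(nCh))

  targetRate <- 150
  nOut <- round(targetRate * trialLength)
  if (ncol(sensorData) < rawRate * trialLength) {
    warning("recording shorter than one trial; returning an empty TrialSet")
    return(new("TrialSet",
               data = array(0, dim = c(0L, nCh, nOut)),
               samplingRate = targetRate, trialLength = trialLength,
               reference = "average", layoutRef = labels))
  }

  bp <- signal::butter(1, c(1, 70) / (rawRate / 2), type = "pass")
  x <- t(apply(sensorData, 1L, function(ch) signal::filtfilt(bp, ch)))

  # DFT notch at line frequency and harmonics below the raw Nyquist
  freqs <- c(50, 100, 150)
  freqs <- freqs[freqs < rawRate / 2]
  if (length(freqs)) {
    tt <- (seq_len(ncol(x)) - 1) / rawRate
    B <- do.call(cbind, lapply(freqs, function(f)
      cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))))
    coef <- solve(crossprod(B), crossprod(B, t(x)))
    x <- x - t(B %*% coef)
  }

  dec <- rawRate %/% targetRate
  if (dec > 1L) {
    aa <- signal::butter(4, 0.8 * (targetRate / 2) / (rawRate / 2), type = "low")
    x <- t(apply(x, 1L, function(ch) signal::filtfilt(aa, ch)))
    x <- x[, seq(1L, ncol(x), by = dec), drop = FALSE]
  }

  nTr <- floor(ncol(x) / nOut)
  dat <- array(0, dim = c(nTr, nCh, nOut))
  for (tr in seq_len(nTr)) {
    seg <- x[, ((tr - 1L) * nOut + 1L):(tr * nOut), drop = FALSE]
    seg <- seg - rowMeans(seg)                    # per-trial demean
    seg <- sweep(seg, 2L, colMeans(seg))          # common average reference
    dat[tr, , ] <- seg
  }
  new("TrialSet", data = dat, samplingRate = targetRate,
      trialLength = trialLength, reference = "average", layoutRef = labels)
}

#' Remove marked trials and their neighbours
#'
#' Each marked trial (artefact or spike-wave-like event) is removed together
#' with its immediate predecessor and successor; boundary trials drop only
#' the neighbours that exist. Survivor order is preserved.
#'
#' @param trials a \linkS4class{TrialSet}.
#' @param marks integer vector of 0-based trial indices (the convention used
#'   in subject records and on-disk mark tables).
#' @return the pruned \linkS4class{TrialSet}.
#' @export
dropMarkedTrials <- function(trials, marks) {
  nTr <- nTrials(trials)
  if (!length(marks)) return(trials)
  marks <- as.integer(marks)
  if (any(marks < 0L) || any(marks >= nTr)) stop("marks out of trial range")
  bad <- unique(sort(c(marks, marks - 1L, marks + 1L)))
  bad <- bad[bad >= 0L & bad < nTr] + 1L
  keep <- setdiff(seq_len(nTr), bad)
  new("TrialSet", data = trials@data[keep, , , drop = FALSE],
      samplingRate = trials@samplingRate, trialLength = trials@trialLength,
      reference = trials@reference, layoutRef = trials@layoutRef)
}

#' Randomly draw clean trials
#'
#' Uniform sample of n trials without replacement, seeded, preserving the
#' original trial order among those selected.
#'
#' @param trials a \linkS4class{TrialSet}.
#' @param n trials to keep.
#' @param seed integer seed.
#' @param subject subject identifier used in the insufficient-data error.
#' @return a \linkS4class{TrialSet} with exactly n trials.
#' @export
selectTrials <- function(trials, n, seed = 1L, subject = "?") {
  nTr <- nTrials(trials)
  if (n > nTr)
    stop(sprintf("insufficient data for subject %s: %d clean trials available, %d requested",
                 subject, nTr, n))
  keep <- sort(withSeed(seed, sample.int(nTr, n)))
  new("TrialSet", data = trials@data[keep, , , drop = FALSE],
      samplingRate = trials@samplingRate, trialLength = trials@trialLength,
      reference = trials@reference, layoutRef = trials@layoutRef)
}
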