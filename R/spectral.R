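#' @include dpss.R
NULL

#' Standard resting-state frequency bands
#'
#' The six-band registry used throughout: delta 2 +/- 2 Hz, theta 6 +/- 2 Hz,
#' alpha 10 +/- 2 Hz, beta1 16 +/- 4 Hz, beta2 25 +/- 4 Hz and low gamma
#' 40 +/- 8 Hz (centre frequency +/- multitaper smoothing).
#'
#' @return named list of \linkS4class{BandSpec} objects.
#' @examples
#' names(defaultBands())
#' @export
defaultBands <- function() {
  spec <- list(delta = c(2, 2), theta = c(6, 2), alpha = c(10, 2),
               beta1 = c(16, 4), beta2 = c(25, 4), gamma = c(40, 8))
  lapply(stats::setNames(names(spec), names(spec)), function(nm)
    new("BandSpec", name = nm, f0 = spec[[nm]][1L], halfBandwidth = spec[[nm]][2L]))
}

#' Multitaper band cross-spectral density
#'
#' Estimates the sensor CSD at one band's centre frequency: each trial is
#' projected onto K = floor(2 T W) - 1 DPSS tapers (time-bandwidth product
#' T W), Fourier transformed, evaluated at the FFT bin nearest f0 (the
#' multitaper already integrates over +/- W), and outer products are averaged
#' over tapers and trials. Degrees of freedom: 2 x trials x tapers.
#'
#' @param trials a \linkS4class{TrialSet}.
#' @param band a \linkS4class{BandSpec}.
#' @return a \linkS4class{SensorCsd} (uV^2/Hz, one-sided density scaling).
#' @export
computeBandCsd <- function(trials, band) {
  fs <- trials@samplingRate
  if (band@f0 + band@halfBandwidth > fs / 2)
    stop("band edge exceeds the Nyquist frequency")
  Tlen <- trials@trialLength
  K <- floor(2 * Tlen * band@halfBandwidth) - 1L
  if (K < 1L) stop("trial length and bandwidth give no usable taper")
  nSamp <- dim(trials@data)[3L]
  nCh <- dim(trials@data)[2L]
  nTr <- dim(trials@data)[1L]
  if (nTr < 1L) stop("no trials available for spectral estimation")
  tapers <- dpssTapers(nSamp, band@halfBandwidth / fs, K)
  # DFT bin nearest f0: only this bin is needed, so the tapered transforms
  # reduce to projections onto tapered complex exponentials (real matmuls)
  bin <- round(band@f0 * Tlen)
  ph <- -2 * pi * bin * (0:(nSamp - 1)) / nSamp
  Fre <- tapers * cos(ph)
  Fim <- tapers * sin(ph)

  accRe <- matrix(0, nCh, nCh)
  accIm <- matrix(0, nCh, nCh)
  for (tr in seq_len(nTr)) {
    x <- trials@data[tr, , , drop = TRUE]     # channels x samples
    if (is.null(dim(x))) x <- matrix(x, nCh, nSamp)
    Xr <- x %*% Fre                           # channels x tapers
    Xi <- x %*% Fim
    accRe <- accRe + tcrossprod(Xr) + tcrossprod(Xi)
    accIm <- accIm + Xi %*% t(Xr) - Xr %*% t(Xi)
  }
  # one-sided density normalization for unit-energy tapers
  csd <- complex(real = accRe, imaginary = accIm) * (2 / (fs * K * nTr))
  csd <- matrix(csd, nCh, nCh)
  csd <- (csd + Conj(t(csd))) / 2             # enforce exact Hermitian symmetry
  new("SensorCsd", matrix = csd, band = band, dof = 2 * nTr * K,
      labels = trials@layoutRef)
}

#' Number of DPSS tapers for a trial length and smoothing
#'
#' The standard convention K = floor(2 T W) - 1.
#'
#' @param trialLength trial length T in seconds.
#' @param halfBandwidth smoothing half-width W in Hz.
#' @return integer taper count.
#' @examples
#' taperCount(10, 2)  # 39
#' @export
taperCount <- function(trialLength, halfBandwidth)
  as.integer(floor(2 * trialLength * halfBandwidth) - 1)

#' Restrict a sensor CSD to a channel subset under re-referencing
#'
#' Selecting a channel subset of average-referenced data and re-referencing
#' to the subset average is linear, so the subset CSD is P C[s, s] P with P
#' the subset centering matrix. This is how lower-density montages reuse the
#' full-montage spectral estimates.
#'
#' @param csd a \linkS4class{SensorCsd}.
#' @param labels channel labels to keep.
#' @return the re-referenced subset \linkS4class{SensorCsd}.
#' @export
subsetCsd <- function(csd, labels) {
  idx <- match(labels, csd@labels)
  if (anyNA(idx)) stop("unknown channel labels in CSD subset")
  m <- csd@matrix[idx, idx, drop = FALSE]
  n <- length(idx)
  P <- diag(n) - matrix(1 / n, n, n)
  m <- P %*% m %*% P
  m <- (m + Conj(t(m))) / 2
  new("SensorCsd", matrix = m, band = csd@band, dof = csd@dof,
      labels = csd@labels[idx])
}
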