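#' @include utils.R
NULL

.dpssCache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first K DPSS tapers of length n for normalized half-bandwidth
#' w (cycles per sample) as the leading eigenvectors of Slepian's tridiagonal
#' commuting matrix. Tapers are unit-energy; results are cached per (n, w, K)
#' within the session since the eigendecomposition dominates the cost.
#'
#' @param n sequence length in samples.
#' @param w normalized half-bandwidth, 0 < w < 1/2 (w = W / samplingRate).
#' @param K number of tapers.
#' @return numeric matrix (n x K), one taper per column.
#' @export
dpssTapers <- function(n, w, K) {
  if (w <= 0 || w >= 0.5) stop("normalized half-bandwidth must be in (0, 1/2)")
  if (K < 1L || K > n) stop("invalid taper count")
  key <- sprintf("%d_%.12g_%d", n, w, K)
  hit <- .dpssCache[[key]]
  if (!is.null(hit)) return(hit)
  t <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  od <- t[-1L] * (n - t[-1L]) / 2
  A <- matrix(0, n, n)
  A[cbind(t + 1, t + 1)] <- dg
  A[cbind(2:n, 1:(n - 1))] <- od
  A[cbind(1:(n - 1), 2:n)] <- od
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(K), drop = FALSE]
  tapers <- sweep(tapers, 2L, sqrt(colSums(tapers^2)), "/")
  # polarity convention: positive mean for symmetric tapers, else positive
  # initial slope (sign is irrelevant for spectra but fixed for determinism)
  for (j in seq_len(K)) {
    s <- sum(tapers[, j])
    if (abs(s) < 1e-8) s <- tapers[2L, j] - tapers[1L, j]
    if (s < 0) tapers[, j] <- -tapers[, j]
  }
  .dpssCache[[key]] <- tapers
  tapers
}
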