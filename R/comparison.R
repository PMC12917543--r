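#' @include AllClasses.R utils.R
NULL

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged).
#'
#' @param a,b equal-length numeric vectors (length >= 3).
#' @return rho.
#' @export
spearmanRank <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  if (length(a) < 3L) stop("at least 3 observations required")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation for constant input")
  stats::cor(a, b, method = "spearman")
}

#' Fisher z transform of a correlation
#'
#' z = atanh(r) = 0.5 log((1 + r) / (1 - r)); variance-stabilizing transform
#' used to compare correlation coefficients.
#'
#' @param r correlation in (-1, 1).
#' @return z.
#' @examples
#' fisherZ(0.5)   # 0.549
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  atanh(r)
}

#' Compare two independent correlations via Fisher z
#'
#' z_diff = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)) with a
#' two-sided normal p-value. The spatial-unit counts of the two maps serve
#' as the effective sample sizes; the shared reference map makes this an
#' approximation (flagged in pipeline reports).
#'
#' @param r1,r2 correlations.
#' @param n1,n2 spatial-unit counts (> 3).
#' @return a \linkS4class{CorrelationComparison}.
#' @export
compareCorrelations <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("unit counts must exceed 3")
  z1 <- fisherZ(r1); z2 <- fisherZ(r2)
  zd <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  new("CorrelationComparison", r1 = r1, r2 = r2, z1 = z1, z2 = z2,
      n1 = n1, n2 = n2, zDiff = zd,
      p = 2 * stats::pnorm(-abs(zd)))
}

# Spin permutation of vertex indices: a uniform random rotation applied to
# the left registration sphere and its sagittal mirror applied to the right;
# each vertex takes the value of the nearest rotated vertex.
spinIndices <- function(sourceSpace) {
  Rl <- randomRotation()
  M <- diag(c(-1, 1, 1))
  Rr <- M %*% Rl %*% M
  idx <- integer(nrow(sourceSpace@sphere))
  for (h in 1:2) {
    vi <- which(sourceSpace@hemi == h)
    S <- sourceSpace@sphere[vi, , drop = FALSE]
    rot <- S %*% t(if (h == 1L) Rl else Rr)
    # nearest original vertex to each rotated position (max cosine)
    idx[vi] <- vi[max.col(S %*% t(rot), ties.method = "first")]
  }
  idx
}

#' Spin test for the correlation of two cortical maps
#'
#' Assesses a Spearman correlation between two vertex maps against a
#' spatially structured null: per rotation, a uniform random 3-D rotation is
#' applied to the left hemisphere's registration sphere and its sagittal
#' mirror to the right hemisphere, the second map is remapped by nearest
#' rotated vertex, and rho is recomputed over all vertices jointly.
#' Two-sided p by the plus-one count formula, so p is never zero.
#'
#' @param mapA,mapB numeric vertex maps (or \linkS4class{VertexMetricMap}),
#'   aligned to \code{sourceSpace}.
#' @param sourceSpace the \linkS4class{SourceSpace} carrying the spheres.
#' @param nRotations number of rotations (>= 99; 1000 in the reference
#'   analyses).
#' @param seed integer seed.
#' @return a \linkS4class{SpinResult}.
#' @export
spinTest <- function(mapA, mapB, sourceSpace, nRotations = 1000L, seed = 1L) {
  if (is(mapA, "VertexMetricMap")) mapA <- mapA@values
  if (is(mapB, "VertexMetricMap")) mapB <- mapB@values
  nV <- nVertices(sourceSpace)
  if (length(mapA) != nV || length(mapB) != nV)
    stop("unsupported input: spin test requires vertex-level maps on the sphere")
  if (nRotations < 99L) stop("at least 99 rotations required")
  rObs <- spearmanRank(mapA, mapB)
  nullR <- withSeed(deriveSeed(seed, 99L), {
    vapply(seq_len(nRotations), function(i) {
      idx <- spinIndices(sourceSpace)
      stats::cor(mapA, mapB[idx], method = "spearman")
    }, numeric(1L))
  })
  p <- (1 + sum(abs(nullR) >= abs(rObs))) / (1 + nRotations)
  new("SpinResult", rObserved = rObs, nullDistribution = nullR,
      nRotations = as.integer(nRotations), pSpin = p)
}
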