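#' @include spectral.R
NULL

#' DICS spatial filters
#'
#' Dynamic Imaging of Coherent Sources: frequency-domain beamformer filters
#' from a sensor CSD and a referenced leadfield. The regularized inverse uses
#' C_r = Re(C) + lambda (trace(Re(C)) / channels) I. Per vertex, the
#' three-orientation filter is A = (L' C_r^-1 L)^-1 L' C_r^-1; the fixed
#' orientation is the dominant eigenvector of the real part of the 3 x 3
#' source CSD A C A^H (sign fixed so the first nonzero component is
#' positive), and the scalar filter is recomputed for that orientation. Each
#' filter has unit gain on its own oriented leadfield column (distortionless
#' constraint).
#'
#' @param csd a \linkS4class{SensorCsd}.
#' @param leadfield a referenced \linkS4class{LeadField} with matching channels.
#' @param lambda regularization as a fraction of mean sensor power
#'   (default 0.05, i.e. 5 percent).
#' @return a \linkS4class{SpatialFilters}.
#' @export
computeDicsFilters <- function(csd, leadfield, lambda = 0.05) {
  if (!leadfield@referenced)
    stop("leadfield must be average-referenced before beamforming")
  if (!identical(csd@labels, leadfield@labels))
    stop("channel sets of CSD and leadfield do not match")
  C <- csd@matrix
  nCh <- nrow(C)
  Cre <- Re(C)
  Cim <- Im(C)
  Cr <- Cre + diag(lambda * sum(diag(Cre)) / nCh, nCh)
  Tmat <- tryCatch(solve(Cr), error = function(e)
    stop("regularized sensor CSD is singular; increase lambda"))
  G <- leadfield@gain
  nV <- ncol(G) %/% 3L
  TG <- Tmat %*% G                              # C_r^-1 L for all vertices

  orient <- matrix(0, nV, 3L)
  Lo <- matrix(0, nCh, nV)                      # oriented leadfield columns
  for (v in seq_len(nV)) {
    j <- (3L * (v - 1L) + 1L):(3L * v)
    Lv <- G[, j, drop = FALSE]
    M <- crossprod(Lv, TG[, j, drop = FALSE])   # L' C_r^-1 L (3 x 3)
    Minv <- tryCatch(solve(M), error = function(e)
      stop(sprintf("numerically rank-deficient leadfield at vertex %d", v)))
    A <- Minv %*% t(TG[, j, drop = FALSE])      # 3 x channels, real
    # real part of the 3 x 3 source CSD A C A^H
    Sre <- A %*% Cre %*% t(A)
    ev <- eigen((Sre + t(Sre)) / 2, symmetric = TRUE)
    u <- ev$vectors[, 1L]
    nz <- which(abs(u) > 1e-12)[1L]
    if (u[nz] < 0) u <- -u
    orient[v, ] <- u
    Lo[, v] <- Lv %*% u
  }
  TL <- Tmat %*% Lo
  denom <- colSums(Lo * TL)                     # l' C_r^-1 l per vertex
  if (any(denom <= 0))
    stop("non-positive beamformer denominator; CSD is not positive definite")
  W <- t(TL) / denom                            # unit-gain scalar filters
  new("SpatialFilters", weights = W, orientations = orient, lambda = lambda,
      labels = csd@labels)
}

#' Beamformer source power map
#'
#' Source power per vertex: Re(w C w^H), clipped at zero against roundoff.
#'
#' @param filters \linkS4class{SpatialFilters}.
#' @param csd \linkS4class{SensorCsd}.
#' @param band,headModel,subject metadata carried into the map.
#' @return a \linkS4class{VertexMetricMap} with metric "power".
#' @export
computeSourcePower <- function(filters, csd, band = csd@band@name,
                               headModel = "canonical", subject = "") {
  W <- filters@weights
  if (ncol(W) != nrow(csd@matrix)) stop("filter/CSD channel mismatch")
  v <- rowSums((W %*% Re(csd@matrix)) * W)
  v[v < 0 & v > -1e-12 * max(abs(v), 1e-300)] <- 0
  new("VertexMetricMap", values = v, metric = "power", band = band,
      headModel = headModel, subject = subject)
}

#' Imaginary-coherency source connectivity
#'
#' Projects the sensor CSD to all source pairs (S = W C W^H), normalizes to
#' coherency c_ij = S_ij / sqrt(S_ii S_jj) and takes the absolute imaginary
#' part, which is insensitive to instantaneous (volume-conducted) mixing.
#' Returns the full vertex x vertex matrix and the per-vertex mean over the
#' remaining vertices.
#'
#' @param filters \linkS4class{SpatialFilters}.
#' @param csd \linkS4class{SensorCsd}.
#' @param band,headModel,subject metadata carried into the map.
#' @return list with elements \code{matrix} (vertices x vertices, zero
#'   diagonal) and \code{map} (a \linkS4class{VertexMetricMap} with metric
#'   "connectivity").
#' @export
computeSourceConnectivity <- function(filters, csd, band = csd@band@name,
                                      headModel = "canonical", subject = "") {
  W <- filters@weights
  if (ncol(W) != nrow(csd@matrix)) stop("filter/CSD channel mismatch")
  Sre <- W %*% Re(csd@matrix) %*% t(W)
  Sim <- W %*% Im(csd@matrix) %*% t(W)
  auto <- diag(Sre)
  if (any(auto <= 0)) stop("degenerate source with zero auto-power")
  denom <- sqrt(outer(auto, auto))
  im <- abs(Sim) / denom
  im <- (im + t(im)) / 2
  diag(im) <- 0
  im[im > 1] <- 1                               # |coherency| <= 1 up to roundoff
  n <- nrow(im)
  mapv <- rowSums(im) / (n - 1L)
  list(matrix = im,
       map = new("VertexMetricMap", values = mapv, metric = "connectivity",
                 band = band, headModel = headModel, subject = subject))
}

#' Global mean of a metric map
#'
#' Arithmetic mean of the per-vertex values: the subject's global estimate.
#'
#' @param map a \linkS4class{VertexMetricMap}.
#' @return numeric(1).
#' @export
globalMean <- function(map) {
  if (length(map@values) == 0L) stop("empty map")
  mean(map@values)
}
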