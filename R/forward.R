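#' @include utils.R
NULL

# Radial transfer coefficients of the three-shell sphere, one per spherical
# harmonic order n, in scalp-radius units. The potential of a dipole at
# fractional radius tau with order-n moment decomposition T_n is
#   V(scalp) = 1/(4 pi sigma1 R^2 p1^2) * sum_n k_n (tau/p1)^(n-1) T_n ,
# with p1 the fractional brain radius. k_n solves the boundary-value problem
# per order: secondary potentials a r^n + b r^-(n+1) in each compartment,
# continuity of potential and radial current at both interfaces, zero radial
# current at the scalp. Unknowns are scaled at their layer edges (growing
# terms at the outer edge, decaying terms at the inner edge) and the primary
# dipole potential is normalized at the brain radius, so all matrix entries
# stay O(n) at any truncation order. For equal conductivities the unscaled
# coefficient reduces to the homogeneous value (2n+1)/n.
radialTransfer <- function(geometry, nTerms) {
  r <- geometry@shellRadii / geometry@shellRadii[3L]
  s <- geometry@conductivities
  key <- paste(c(format(r, digits = 15), format(s, digits = 15), nTerms),
               collapse = "|")
  hit <- .radialCache[[key]]
  if (!is.null(hit)) return(hit)
  p1 <- r[1L]; p2 <- r[2L]
  q1 <- p1 / p2
  k <- vapply(seq_len(nTerms), function(n) {
    m <- matrix(0, 5L, 5L)
    rhs <- numeric(5L)
    # unknowns: A1 p1^n, A2 p2^n, B2 p1^-(n+1), A3, B3 p2^-(n+1)
    # potential continuity at brain/skull boundary
    m[1L, ] <- c(1, -q1^n, -1, 0, 0)
    rhs[1L] <- -1
    # radial current continuity at brain/skull boundary (times p1)
    m[2L, ] <- c(s[1L] * n, -s[2L] * n * q1^n, s[2L] * (n + 1), 0, 0)
    rhs[2L] <- s[1L] * (n + 1)
    # potential continuity at skull/scalp boundary
    m[3L, ] <- c(0, 1, q1^(n + 1), -p2^n, -1)
    # radial current continuity at skull/scalp boundary (times p2)
    m[4L, ] <- c(0, s[2L] * n, -s[2L] * (n + 1) * q1^(n + 1),
                 -s[3L] * n * p2^n, s[3L] * (n + 1))
    # insulating outer boundary
    m[5L, ] <- c(0, 0, 0, n, -(n + 1) * p2^(n + 1))
    x <- solve(m, rhs)
    x[4L] + x[5L] * p2^(n + 1)
  }, numeric(1L))
  out <- list(k = k, p1 = p1)
  .radialCache[[key]] <- out
  out
}

.radialCache <- new.env(parent = emptyenv())

#' Compute the three-shell sphere EEG leadfield
#'
#' Analytic forward solution for dipoles inside a three-compartment
#' concentric-sphere head: a truncated Legendre series whose per-order radial
#' coefficients solve the layered boundary-value problem. The gain maps a
#' unit dipole moment (A m) along each Cartesian axis at each source vertex
#' to channel potentials (V). The result is unreferenced; apply
#' \code{\link{averageReference}} before beamforming.
#'
#' @param layout \linkS4class{ElectrodeLayout}; electrode directions are
#'   placed on the geometry's scalp shell.
#' @param sourceSpace \linkS4class{SourceSpace}; anatomical coordinates are
#'   scaled by the brain shell radius.
#' @param geometry \linkS4class{HeadGeometry}.
#' @param nTerms series truncation order (>= 20; default 60).
#' @return a \linkS4class{LeadField}.
#' @examples
#' lay <- buildLayout(32, seed = 1)
#' ss <- buildSourceSpace(42, nRegions = 4, nNetworks = 2, seed = 1)
#' lf <- computeLeadfield(lay, ss, new("HeadGeometry"))
#' dim(gainMatrix(lf))
#' @export
computeLeadfield <- function(layout, sourceSpace, geometry, nTerms = 60L) {
  if (nTerms < 20L) stop("nTerms must be at least 20")
  R <- geometry@shellRadii[3L]
  rBrain <- geometry@shellRadii[1L]
  ehat <- normalizeRows(layout@positions)
  anat <- sourceSpace@anatomical
  bfrac <- sqrt(rowSums(anat^2))
  if (any(bfrac >= 1 - 1e-9))
    stop("source vertices must lie strictly inside the brain shell")
  vhat <- anat / bfrac
  tau <- bfrac * rBrain / R
  nCh <- nrow(ehat); nV <- nrow(anat)

  rt <- radialTransfer(geometry, nTerms)
  kn <- rt$k
  tau <- tau / rt$p1                      # primary normalized at brain radius
  U <- tcrossprod(ehat, vhat)             # cos(angle electrode, vertex)
  taumat <- matrix(tau, nCh, nV, byrow = TRUE)

  Pprev <- matrix(1, nCh, nV)             # P_0
  Pcur <- U                               # P_1
  dPprev <- matrix(0, nCh, nV)            # P_0'
  dPcur <- matrix(1, nCh, nV)             # P_1'
  coef <- matrix(1, nCh, nV)              # tau^(n-1)
  alpha <- kn[1L] * (Pcur - U * dPcur)    # n=1: n P_n - u P_n'
  beta <- kn[1L] * dPcur
  if (nTerms > 1L) for (n in 2:nTerms) {
    Pnext <- ((2 * n - 1) * U * Pcur - (n - 1) * Pprev) / n
    dPnext <- dPprev + (2 * n - 1) * Pcur
    Pprev <- Pcur; Pcur <- Pnext
    dPprev <- dPcur; dPcur <- dPnext
    coef <- coef * taumat
    alpha <- alpha + kn[n] * coef * (n * Pcur - U * dPcur)
    beta <- beta + kn[n] * coef * dPcur
  }

  scale <- 1 / (4 * pi * geometry@conductivities[1L] * R^2 * rt$p1^2)
  gain <- matrix(0, nCh, 3L * nV)
  for (c in 1:3) {
    Gc <- alpha * matrix(vhat[, c], nCh, nV, byrow = TRUE) + beta * ehat[, c]
    gain[, seq(c, 3L * nV, by = 3L)] <- scale * Gc
  }
  new("LeadField", gain = gain, referenced = FALSE, labels = layout@labels)
}

#' Apply the common average reference to a leadfield
#'
#' Subtracts the channel mean from every gain column, matching sensor data
#' that are re-referenced to the common average. Idempotent; constant
#' columns map to zero.
#'
#' @param leadfield a \linkS4class{LeadField}.
#' @return the referenced \linkS4class{LeadField}.
#' @export
averageReference <- function(leadfield) {
  g <- leadfield@gain
  g <- g - matrix(colMeans(g), nrow(g), ncol(g), byrow = TRUE)
  new("LeadField", gain = g, referenced = TRUE, labels = leadfield@labels)
}

# Potential at given electrodes for one dipole (position in metres relative
# to the head centre, moment in A m); same series as computeLeadfield but for
# a single source. Used by the simulator and handy for point evaluations.
dipolePotential <- function(electrodeDirs, dipolePos, moment, geometry,
                            nTerms = 60L) {
  R <- geometry@shellRadii[3L]
  b <- sqrt(sum(dipolePos^2))
  if (b >= geometry@shellRadii[1L]) stop("dipole must lie inside the brain shell")
  vhat <- dipolePos / b
  rt <- radialTransfer(geometry, nTerms)
  kn <- rt$k
  tau <- (b / R) / rt$p1
  u <- as.vector(electrodeDirs %*% vhat)
  mr <- sum(moment * vhat)
  mc <- as.vector(electrodeDirs %*% moment) - u * mr  # m . (e_hat - u v_hat)
  Pprev <- rep(1, length(u)); Pcur <- u
  dPprev <- rep(0, length(u)); dPcur <- rep(1, length(u))
  acc <- kn[1L] * (mr * Pcur + mc * dPcur)
  tpow <- 1
  if (nTerms > 1L) for (n in 2:nTerms) {
    Pnext <- ((2 * n - 1) * u * Pcur - (n - 1) * Pprev) / n
    dPnext <- dPprev + (2 * n - 1) * Pcur
    Pprev <- Pcur; Pcur <- Pnext
    dPprev <- dPcur; dPcur <- dPnext
    tpow <- tpow * tau
    acc <- acc + kn[n] * tpow * (n * mr * Pcur + mc * dPcur)
  }
  acc / (4 * pi * geometry@conductivities[1L] * R^2 * rt$p1^2)
}
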