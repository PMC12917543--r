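#' @include utils.R
NULL

# Ideal 10-20 anchor directions on the unit sphere, head coordinates
# (x right, y anterior, z superior). Polar angle from vertex; signed azimuth
# from anterior midline, positive to the right. F3/F4 and P3/P4 follow the
# montage construction rule: great-circle midpoints of (Fz, F7/F8) and
# (Pz, P7/P8).
tenTwentyAnchors <- function() {
  dir <- function(polar, az) {
    p <- polar * pi / 180; a <- az * pi / 180
    c(sin(p) * sin(a), sin(p) * cos(a), cos(p))
  }
  mid <- function(u, v) { w <- u + v; w / sqrt(sum(w^2)) }
  d <- list(
    Cz = dir(0, 0), Fz = dir(45, 0), Pz = dir(45, 180),
    C3 = dir(45, -90), C4 = dir(45, 90),
    Fp1 = dir(90, -18), Fp2 = dir(90, 18),
    F7 = dir(90, -54), F8 = dir(90, 54),
    T7 = dir(90, -90), T8 = dir(90, 90),
    P7 = dir(90, -126), P8 = dir(90, 126),
    O1 = dir(90, -162), O2 = dir(90, 162))
  d$F3 <- mid(d$Fz, d$F7); d$F4 <- mid(d$Fz, d$F8)
  d$P3 <- mid(d$Pz, d$P7); d$P4 <- mid(d$Pz, d$P8)
  do.call(rbind, d)
}

# Greedy distance assignment of anchor directions to candidate points:
# each anchor gets the nearest still-free candidate, closest pairs first.
assignAnchors <- function(anchorDirs, candidateDirs) {
  nA <- nrow(anchorDirs); nC <- nrow(candidateDirs)
  d <- 2 - 2 * tcrossprod(anchorDirs, candidateDirs)  # squared chord distance
  ord <- order(d)
  takenA <- logical(nA); takenC <- logical(nC)
  out <- integer(nA)
  for (k in ord) {
    i <- (k - 1L) %% nA + 1L; j <- (k - 1L) %/% nA + 1L
    if (!takenA[i] && !takenC[j]) {
      out[i] <- j; takenA[i] <- TRUE; takenC[j] <- TRUE
      if (all(takenA)) break
    }
  }
  out
}

#' Build a quasi-uniform spherical-cap electrode layout
#'
#' Generates \code{nChannels} positions covering the upper scalp (polar angle
#' up to \code{capAngle}) with a mirror-symmetric Fibonacci-style lattice:
#' a midline arc plus golden-angle points on the right half-cap mirrored to
#' the left. The 19 classical 10-20 anchor directions are snapped to their
#' nearest lattice points, renamed and flagged protected. The seed controls a
#' small symmetric jitter of the lattice, emulating that real nets are not
#' perfectly regular.
#'
#' @param nChannels integer, total channels (>= 19).
#' @param scalpRadius scalp shell radius in metres.
#' @param seed integer seed for the lattice jitter.
#' @param capAngle maximal polar angle of coverage (radians), default 120 degrees.
#' @return an \linkS4class{ElectrodeLayout}.
#' @examples
#' lay <- buildLayout(64, seed = 1)
#' nChannels(lay)
#' protectedChannels(lay)
#' @export
buildLayout <- function(nChannels, scalpRadius = 0.1, seed = 1L,
                        capAngle = 2 * pi / 3) {
  if (nChannels < 19L) stop("at least 19 channels required (10-20 anchors)")
  nChannels <- as.integer(nChannels)
  m0 <- max(3L, as.integer(round(0.8 * sqrt(nChannels))))
  if ((m0 %% 2L) != (nChannels %% 2L)) m0 <- m0 + 1L
  nMid <- m0
  nPair <- (nChannels - nMid) %/% 2L
  if (nPair < 8L) stop("layout too small to host the lateral 10-20 anchors")

  withSeed(deriveSeed(seed, 424243L), {
    # midline arc from anterior rim over the vertex to posterior rim
    alpha <- -capAngle + (seq_len(nMid) - 0.5) / nMid * 2 * capAngle
    alpha <- alpha + stats::rnorm(nMid, sd = 0.02 * 2 * capAngle / nMid)
    midDirs <- cbind(0, sin(alpha), cos(alpha))
    # right half-cap golden-angle lattice, mirrored to the left
    i <- seq_len(nPair)
    z <- 1 - (i - 0.5) / nPair * (1 - cos(capAngle))
    z <- pmin(1 - 1e-9, pmax(cos(capAngle),
      z + stats::rnorm(nPair, sd = 0.02 * (1 - cos(capAngle)) / nPair)))
    margin <- 0.12
    phi <- margin + (i * 2.399963229728653) %% (pi - 2 * margin)
    phi <- pmin(pi - margin, pmax(margin, phi + stats::rnorm(nPair, sd = 0.01)))
    s <- sqrt(1 - z^2)
    rightDirs <- cbind(s * sin(phi), s * cos(phi), z)
  })
  leftDirs <- rightDirs * rep(c(-1, 1, 1), each = nPair)

  dirs <- rbind(midDirs, rightDirs, leftDirs)
  dimnames(dirs) <- NULL
  labels <- c(sprintf("M%03d", seq_len(nMid)),
              sprintf("R%03d", seq_len(nPair)),
              sprintf("L%03d", seq_len(nPair)))
  mirror <- c(labels[seq_len(nMid)],                      # midline: self
              sprintf("L%03d", seq_len(nPair)),
              sprintf("R%03d", seq_len(nPair)))

  anchors <- tenTwentyAnchors()
  midA <- c("Cz", "Fz", "Pz")
  rightA <- c("Fp2", "F4", "F8", "C4", "T8", "P4", "P8", "O2")
  leftA <- c("Fp1", "F3", "F7", "C3", "T7", "P3", "P7", "O1")
  iMid <- assignAnchors(anchors[midA, , drop = FALSE], midDirs)
  iRight <- assignAnchors(anchors[rightA, , drop = FALSE], rightDirs)
  labels[iMid] <- midA
  labels[nMid + iRight] <- rightA
  labels[nMid + nPair + iRight] <- leftA       # mirror partner gets left name
  mirror <- labels[match(mirror, c(sprintf("M%03d", seq_len(nMid)),
                                   sprintf("R%03d", seq_len(nPair)),
                                   sprintf("L%03d", seq_len(nPair))))]
  names(mirror) <- labels
  protected <- c(midA, rightA, leftA)

  new("ElectrodeLayout", labels = labels,
      positions = dirs * scalpRadius, protected = protected,
      mirror = mirror, scalpRadius = scalpRadius)
}

# Keep only the channels in `keep` (labels), preserving original order.
layoutSubset <- function(layout, keep) {
  idx <- which(layout@labels %in% keep)
  lab <- layout@labels[idx]
  mir <- layout@mirror[lab]
  orphan <- !(mir %in% lab)
  mir[orphan] <- lab[orphan]  # partner removed: pair with self
  new("ElectrodeLayout", labels = lab,
      positions = layout@positions[idx, , drop = FALSE],
      protected = intersect(layout@protected, lab),
      mirror = mir, scalpRadius = layout@scalpRadius)
}

#' Reduce an electrode layout by iterative distance-based removal
#'
#' Removes channels from the densest scalp regions one pair at a time: the
#' non-protected channel with the smallest nearest-neighbour distance is
#' removed (ties broken by lexicographically smallest label), immediately
#' followed by its contralateral mirror partner. Protected (10-20 anchor)
#' channels are never removed. Reduction is a prefix cut of one deterministic
#' removal sequence, so results are nested: reducing to 64 and then to 32
#' gives the same channels as reducing to 32 directly. When the requested
#' count falls between the two members of a pair, a final single removal
#' without the mirror partner is performed.
#'
#' @param layout an \linkS4class{ElectrodeLayout}.
#' @param targetCount channels to keep; at least the number of protected
#'   channels, at most the current count.
#' @return the reduced \linkS4class{ElectrodeLayout}.
#' @examples
#' lay <- buildLayout(64, seed = 1)
#' lay32 <- reduceLayout(lay, 32)
#' all(protectedChannels(lay) %in% channelLabels(lay32))
#' @export
reduceLayout <- function(layout, targetCount) {
  targetCount <- as.integer(targetCount)
  n <- nChannels(layout)
  if (targetCount > n) stop("targetCount exceeds current channel count")
  if (targetCount < length(layout@protected))
    stop("targetCount must be at least the number of protected channels")
  if (targetCount == n) return(layout)

  lab <- layout@labels
  pos <- layout@positions
  prot <- lab %in% layout@protected
  mir <- layout@mirror
  alive <- rep(TRUE, n)
  names(alive) <- lab
  pending <- NA_character_
  left <- n

  D <- as.matrix(stats::dist(pos))
  diag(D) <- Inf

  while (left > targetCount) {
    if (!is.na(pending)) {
      drop <- pending
      pending <- NA_character_
    } else {
      cand <- which(alive & !prot)
      nn <- apply(D[cand, alive, drop = FALSE], 1L, min)
      best <- lab[cand[nn == min(nn)]]
      drop <- sort(best)[1L]  # deterministic tie-break
      partner <- unname(mir[drop])
      if (!identical(partner, drop) && alive[partner]) pending <- partner
    }
    i <- match(drop, lab)
    alive[i] <- FALSE
    D[i, ] <- Inf
    D[, i] <- Inf
    left <- left - 1L
  }
  layoutSubset(layout, lab[alive])
}
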