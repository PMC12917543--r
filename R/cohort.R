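#' @include forward.R spectral.R
NULL

#' Construct a synthetic cohort specification
#'
#' Defaults describe the reference study conditions: 35 patients vs 54
#' controls recorded with a 256-channel montage at 600 Hz, a 1002-vertex-per-
#' hemisphere source space with 68 regions and 14 networks, theta-band source
#' amplitude elevated by a factor 1.4 in the active regions of patients
#' (five mirror-symmetric region pairs), 90-degree-lagged theta coupling
#' (+0.3) between every left-right pair of the active set, sensor SNR 3,
#' 2 percent per-subject head-scale jitter, two sites, and spike-wave-like
#' burst marks in about 37 percent of patients. The default 400 s recording
#' yields 40 trials, leaving at least 30 clean trials (the amount shown to
#' give reliable spectral metrics) after exclusions.
#'
#' @param nPatients,nControls group sizes.
#' @param nChannels montage size.
#' @param verticesPerHemisphere source mesh resolution (10 k^2 + 2).
#' @param nRegions,nNetworks parcellation sizes.
#' @param samplingRate raw rate in Hz, integer multiple of 150.
#' @param recordingLength seconds.
#' @param bandEffects named patient/control amplitude ratios per band.
#' @param couplingEffect named patient coupling increments per band.
#' @param activeRegions region labels carrying the amplitude effect.
#' @param couplingPairs two-column matrix of coupled region labels.
#' @param snr sensor signal-to-noise amplitude ratio.
#' @param geometryJitter relative s.d. of per-subject geometry perturbation.
#' @param nSites number of recording sites.
#' @param ageMean,ageSd age distribution in years.
#' @param markRate fraction of patients with burst-marked trials.
#' @param sourceMode "vertex" (an independent source at every cortical
#'   vertex; the default, required for spatial-recovery studies) or
#'   "region" (one source per region at its centroid vertex; a coarse,
#'   much cheaper background for global-metric studies such as null
#'   calibrations).
#' @param seed integer master seed.
#' @return a \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nPatients = 35L, nControls = 54L, nChannels = 256L,
                       verticesPerHemisphere = 1002L, nRegions = 68L,
                       nNetworks = 14L, samplingRate = 600,
                       recordingLength = 400,
                       bandEffects = c(delta = 1, theta = 1.4, alpha = 1,
                                       beta1 = 1, beta2 = 1, gamma = 1),
                       couplingEffect = c(delta = 0, theta = 0.3, alpha = 0,
                                          beta1 = 0, beta2 = 0, gamma = 0),
                       activeRegions = NULL, couplingPairs = NULL,
                       snr = 3, geometryJitter = 0.02, nSites = 2L,
                       ageMean = 31, ageSd = 12, markRate = 0.37,
                       sourceMode = c("vertex", "region"), seed = 1L) {
  sourceMode <- match.arg(sourceMode)
  nR2 <- as.integer(nRegions) %/% 2L
  if (is.null(activeRegions)) {
    # default effect topography: five mirror-symmetric region pairs
    # (scattered bilateral patches, keeping the spatial null of the spin
    # test well-populated)
    base <- seq_len(min(5L, nR2))
    activeRegions <- as.integer(c(base, base + nR2))
  }
  if (is.null(couplingPairs)) {
    # lagged coupling between every left-right pair of the active set,
    # emulating broadly raised interhemispheric synchrony
    base <- seq_len(min(5L, nR2))
    cp <- expand.grid(left = base, right = base + nR2)
    couplingPairs <- cbind(as.integer(cp$left), as.integer(cp$right))
  }
  new("CohortSpec", nPatients = as.integer(nPatients),
      nControls = as.integer(nControls), nChannels = as.integer(nChannels),
      verticesPerHemisphere = as.integer(verticesPerHemisphere),
      nRegions = as.integer(nRegions), nNetworks = as.integer(nNetworks),
      samplingRate = samplingRate, recordingLength = recordingLength,
      bandEffects = bandEffects, couplingEffect = couplingEffect,
      activeRegions = as.integer(activeRegions),
      couplingPairs = couplingPairs, snr = snr,
      geometryJitter = geometryJitter, nSites = as.integer(nSites),
      ageMean = ageMean, ageSd = ageSd, markRate = markRate,
      sourceMode = sourceMode, seed = as.integer(seed))
}

.cohortCache <- new.env(parent = emptyenv())

# Shared cohort-level structures: source space, template geometry and layout,
# per-region source dipoles and the ground-truth maps. Cached per spec.
cohortContext <- function(spec) {
  key <- paste(spec@seed, spec@nChannels, spec@verticesPerHemisphere,
               spec@nRegions, spec@nNetworks, sep = "_")
  hit <- .cohortCache[[key]]
  if (!is.null(hit)) return(hit)
  ss <- buildSourceSpace(spec@verticesPerHemisphere, spec@nRegions,
                         spec@nNetworks, seed = deriveSeed(spec@seed, 1L))
  geometry <- new("HeadGeometry")
  layout <- buildLayout(spec@nChannels, scalpRadius = geometry@shellRadii[3L],
                        seed = deriveSeed(spec@seed, 2L))
  # one dipole per region at the vertex closest to the region centroid,
  # oriented along the local surface normal of its hemisphere sphere
  srcVertex <- vapply(seq_len(spec@nRegions), function(r) {
    idx <- which(ss@region == r)
    ctr <- colMeans(ss@sphere[idx, , drop = FALSE])
    idx[which.max(ss@sphere[idx, , drop = FALSE] %*% ctr)]
  }, integer(1L))
  # per-vertex surface normals of the hemisphere spheres: the stored
  # registration coordinates (already sagittally mirrored on the right)
  ctx <- list(sourceSpace = ss, geometry = geometry, layout = layout,
              srcVertex = srcVertex, normals = ss@sphere)
  .cohortCache[[key]] <- ctx
  ctx
}

# Oriented per-vertex leadfield (channels x vertices) for the simulator:
# every cortical vertex is an independent 10 nAm surface-normal dipole,
# average referenced.
sourceGain <- function(ctx, geometry, layout) {
  ss <- ctx$sourceSpace
  lf <- computeLeadfield(layout, ss, geometry)
  nV <- nVertices(ss)
  nCh <- nrow(lf@gain)
  idx <- 3L * (seq_len(nV) - 1L)
  Lo <- lf@gain[, idx + 1L, drop = FALSE] * matrix(ctx$normals[, 1L], nCh, nV, byrow = TRUE) +
    lf@gain[, idx + 2L, drop = FALSE] * matrix(ctx$normals[, 2L], nCh, nV, byrow = TRUE) +
    lf@gain[, idx + 3L, drop = FALSE] * matrix(ctx$normals[, 3L], nCh, nV, byrow = TRUE)
  g <- Lo * 1e-8
  g - matrix(colMeans(g), nCh, nV, byrow = TRUE)
}

# Narrowband stochastic oscillator: a slowly varying complex Gaussian
# envelope (bandwidth `bw`) carried at f0. The envelope makes the amplitude
# modulated and the phase diffuse, so distinct sources are mutually
# incoherent within a trial (a pure sinusoid would make every source of a
# band fully coherent with every other and provoke beamformer
# cancellation). The quadrature component is the exact 90-degree-lagged
# copy used for lagged coupling.
oscillator <- function(nSamp, rate, f0, bw = 1) {
  o <- oscMat(nSamp, rate, f0, 1L, bw = bw, qCols = 1L)
  list(i = as.vector(o$i), q = as.vector(o$q))
}

# Matrix of n independent narrowband oscillators (nSamp x n): complex
# Gaussian spectra restricted to |f| <= bw, inverse-transformed and carried
# at f0. Columns are unit variance. The quadrature (exact 90-degree lag) is
# returned alongside; it costs no extra random draws.
oscMat <- function(nSamp, rate, f0, n, bw = 1, qCols = integer(0L)) {
  m <- nSamp + (nSamp %% 2L)
  k <- 0:(m - 1)
  fs <- ifelse(k <= m / 2, k, k - m) * (rate / m)
  sel <- which(abs(fs) <= bw)
  Z <- matrix(0 + 0i, m, n)
  Z[sel, ] <- matrix(complex(real = stats::rnorm(length(sel) * n),
                             imaginary = stats::rnorm(length(sel) * n)),
                     length(sel), n)
  a <- stats::mvfft(Z, inverse = TRUE)[seq_len(nSamp), , drop = FALSE]
  t <- (seq_len(nSamp) - 1) / rate
  cs <- cos(2 * pi * f0 * t); sn <- sin(2 * pi * f0 * t)
  i <- Re(a) * cs - Im(a) * sn
  sdv <- sqrt(colMeans(i^2) - colMeans(i)^2)
  i <- sweep(i, 2L, sdv, "/")
  q <- NULL
  if (length(qCols)) {
    aq <- a[, qCols, drop = FALSE]
    q <- sweep(Re(aq) * sn + Im(aq) * cs, 2L, sdv[qCols], "/")
  }
  list(i = i, q = q, qCols = qCols)
}

# Matrix of n independent 1/f-amplitude noise series (nSamp x n), unit
# variance per column.
pinkMat <- function(nSamp, rate, n) {
  m <- nSamp + (nSamp %% 2L)
  W <- matrix(stats::rnorm(m * n), m, n)
  k <- 0:(m - 1)
  f <- pmin(k, m - k) * (rate / m)
  shape <- 1 / sqrt(pmax(f, rate / m))
  shape[1L] <- 0
  Y <- Re(stats::mvfft(stats::mvfft(W) * shape, inverse = TRUE))[seq_len(nSamp), , drop = FALSE] / m
  sdv <- sqrt(colMeans(Y^2) - colMeans(Y)^2)
  sweep(Y, 2L, sdv, "/")
}

#' Simulate one subject's continuous recording
#'
#' Draws the subject's perturbed head geometry and electrode positions,
#' synthesizes independent source activity at every cortical vertex (1/f
#' background plus one narrowband stochastic oscillator per band), scales
#' patient oscillator amplitudes at active-region vertices by the band
#' effects, adds 90-degree-lagged coupling between matched vertices of the
#' designated region pairs for patients, projects through the subject's own leadfield and adds white
#' sensor noise at the configured SNR. Spike-wave-like high-amplitude 3 Hz
#' bursts are injected into randomly chosen trials of marked patients and
#' recorded as 0-based trial marks. Deterministic given (spec seed,
#' subject index).
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param index subject index, 1-based; patients come first.
#' @return a \linkS4class{SubjectRecord} (sensor data in microvolts).
#' @export
simulateSubject <- function(spec, index) {
  nTot <- spec@nPatients + spec@nControls
  if (index < 1L || index > nTot) stop("subject index out of range")
  ctx <- cohortContext(spec)
  group <- if (index <= spec@nPatients) "patient" else "control"
  gIdx <- if (group == "patient") index else index - spec@nPatients
  gSize <- if (group == "patient") spec@nPatients else spec@nControls
  # balanced block assignment (independent of the round-robin site cycle)
  sex <- as.integer(gIdx > ceiling(gSize / 2))
  site <- (index - 1L) %% spec@nSites + 1L
  bands <- defaultBands()
  rate <- spec@samplingRate
  nSamp <- round(spec@recordingLength * rate)


  withSeed(deriveSeed(spec@seed, 1000L + index), {
    age <- max(10, stats::rnorm(1L, spec@ageMean, spec@ageSd))
    # per-subject geometry jitter (individual head model ground truth):
    # a common head-scale factor, so shell ordering and relative skull
    # thickness are preserved (independent per-shell jitter would let the
    # thin skull layer fluctuate wildly and dominate sensor power)
    r <- ctx$geometry@shellRadii * (1 + stats::rnorm(1L, sd = spec@geometryJitter))
    geom <- new("HeadGeometry", shellRadii = r,
                conductivities = ctx$geometry@conductivities,
                centre = ctx$geometry@centre)
    pos <- ctx$layout@positions
    pos <- pos + matrix(stats::rnorm(length(pos),
                                     sd = spec@geometryJitter * geom@shellRadii[3L] / 2),
                        nrow(pos), 3L)
    pos <- normalizeRows(pos) * geom@shellRadii[3L]
    lay <- new("ElectrodeLayout", labels = ctx$layout@labels, positions = pos,
               protected = ctx$layout@protected, mirror = ctx$layout@mirror,
               scalpRadius = geom@shellRadii[3L])

    # source activity (samples x vertices): every cortical vertex carries an
    # independent 1/f background plus one stochastic oscillator per band;
    # patients get the band-effect amplitude ratio at active-region vertices,
    # and each vertex of a coupled target region receives the
    # 90-degree-lagged copy of a matched source-region vertex's oscillator
    # scaled by the coupling increment (power in the source region is
    # untouched by coupling).
    srcIdx <- if (spec@sourceMode == "region") ctx$srcVertex
      else seq_len(nVertices(ctx$sourceSpace))
    reg <- ctx$sourceSpace@region[srcIdx]
    nV <- length(reg)
    activeMask <- reg %in% spec@activeRegions
    isPatient <- group == "patient"
    S <- 2 * pinkMat(nSamp, rate, nV)
    for (b in bands) {
      ce <- spec@couplingEffect[[b@name]]
      qCols <- if (isPatient && ce != 0 && nrow(spec@couplingPairs))
        which(reg %in% spec@couplingPairs[, 1L]) else integer(0L)
      o <- oscMat(nSamp, rate, b@f0, nV, qCols = qCols)
      eff <- spec@bandEffects[[b@name]]
      S <- S + o$i
      if (isPatient && eff != 1) {
        act <- which(activeMask)
        S[, act] <- S[, act] + (eff - 1) * o$i[, act, drop = FALSE]
      }
      if (length(qCols)) {
        amp <- rep(1, nV)
        if (isPatient) amp[activeMask] <- eff
        for (p in seq_len(nrow(spec@couplingPairs))) {
          vA <- which(reg == spec@couplingPairs[p, 1L])
          vB <- which(reg == spec@couplingPairs[p, 2L])
          if (!length(vA) || !length(vB)) next
          vAm <- vA[(seq_along(vB) - 1L) %% length(vA) + 1L]
          qa <- o$q[, match(vAm, qCols), drop = FALSE]
          S[, vB] <- S[, vB] + ce * sweep(qa, 2L, amp[vAm], "*")
        }
      }
    }

    G <- sourceGain(ctx, geom, lay)[, srcIdx, drop = FALSE]  # V per source
    X <- t(S %*% t(G)) * 1e6                   # channels x samples, microvolts
    # noise floor fixed by the control generative law (background variance 4
    # plus one unit-variance oscillator per band), not by the subject's own
    # signal power: a recording system's noise does not grow with source
    # amplitude, and subject-dependent noise would confound group effects
    baseVar <- 4 + length(bands)
    sigRms <- sqrt(baseVar * ncol(G) * mean(G^2)) * 1e6
    X <- X + matrix(stats::rnorm(length(X), sd = sigRms / spec@snr),
                    nrow(X), ncol(X))

    # spike-wave-like bursts in marked patient trials
    marks <- integer(0L)
    nTr <- floor(spec@recordingLength / 10)
    if (group == "patient" && nTr > 0L && stats::runif(1L) < spec@markRate) {
      nMark <- min(nTr, sample.int(3L, 1L))
      marks <- sort(sample.int(nTr, nMark) - 1L)
      topo <- rowMeans(G[, reg == spec@activeRegions[1L], drop = FALSE]) * 1e6
      for (mk in marks) {
        idx <- (mk * 10 * rate + 1L):((mk + 1L) * 10 * rate)
        t <- (seq_along(idx) - 1) / rate
        burst <- sin(2 * pi * 3 * t) + 0.5 * sin(2 * pi * 6 * t)
        X[, idx] <- X[, idx] + outer(as.vector(topo), burst) * 8 * sigRms /
          max(abs(topo))
      }
    }

    new("SubjectRecord", id = sprintf("S%03d", index), group = group,
        age = age, sex = as.integer(sex), site = as.integer(site),
        geometry = geom, layout = lay, sensorData = X, samplingRate = rate,
        marks = marks)
  })
}

#' Simulate a full two-group cohort
#'
#' Generates all subjects (patients first) plus the ground-truth effect
#' topography. For large configurations prefer simulating subjects one at a
#' time with \code{\link{simulateSubject}} and discarding raw data after
#' preprocessing; this convenience materializes every recording in memory.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return list with \code{subjects} (list of \linkS4class{SubjectRecord}),
#'   \code{truth} (a \linkS4class{GroundTruth}) and \code{covariates}
#'   (data.frame: subject, group, age, sex, site).
#' @export
simulateCohort <- function(spec) {
  nTot <- spec@nPatients + spec@nControls
  subjects <- lapply(seq_len(nTot), function(i) simulateSubject(spec, i))
  cov <- data.frame(
    subject = vapply(subjects, function(s) s@id, character(1L)),
    group = vapply(subjects, function(s) s@group, character(1L)),
    age = vapply(subjects, function(s) s@age, numeric(1L)),
    sex = vapply(subjects, function(s) s@sex, integer(1L)),
    site = vapply(subjects, function(s) s@site, integer(1L)))
  list(subjects = subjects, truth = groundTruth(spec), covariates = cov)
}

#' Ground-truth effect maps of a cohort specification
#'
#' Vertex-level expected direction of the patient-minus-control difference:
#' for power, (band effect - 1) inside the active regions; for connectivity,
#' the coupling increment inside the coupled regions. Zero elsewhere.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return a \linkS4class{GroundTruth}.
#' @export
groundTruth <- function(spec) {
  ctx <- cohortContext(spec)
  reg <- ctx$sourceSpace@region
  powerMaps <- list(); connMaps <- list()
  for (b in names(spec@bandEffects)) {
    if (spec@bandEffects[[b]] != 1)
      powerMaps[[b]] <- (spec@bandEffects[[b]] - 1) *
        as.numeric(reg %in% spec@activeRegions)
  }
  coupled <- unique(as.vector(spec@couplingPairs))
  for (b in names(spec@couplingEffect)) {
    if (spec@couplingEffect[[b]] != 0)
      connMaps[[b]] <- spec@couplingEffect[[b]] *
        as.numeric(reg %in% coupled)
  }
  new("GroundTruth", powerMaps = powerMaps, connMaps = connMaps,
      activeRegions = spec@activeRegions, couplingPairs = spec@couplingPairs)
}
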