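# Shared fixtures, built once per test session.

.fix <- new.env(parent = emptyenv())

fixLayout <- function(n = 64L, seed = 1L) {
  key <- sprintf("lay_%d_%d", n, seed)
  if (is.null(.fix[[key]])) .fix[[key]] <- buildLayout(n, seed = seed)
  .fix[[key]]
}

fixSourceSpace <- function(v = 162L, nr = 68L, nn = 14L, seed = 1L) {
  key <- sprintf("ss_%d_%d_%d_%d", v, nr, nn, seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- buildSourceSpace(v, nRegions = nr, nNetworks = nn, seed = seed)
  .fix[[key]]
}

fixGeometry <- function() new("HeadGeometry")

# Independent oracle: closed-form surface potential of a dipole inside a
# homogeneous conducting sphere, derived by summing the Legendre series with
# generating functions (independent of the package's boundary-value route).
homogeneousSpherePotential <- function(electrodeDirs, dipolePos, moment,
                                       sigma, R) {
  b <- sqrt(sum(dipolePos^2))
  vh <- dipolePos / b
  f <- b / R
  u <- as.vector(electrodeDirs %*% vh)
  mr <- sum(moment * vh)
  mc <- as.vector(electrodeDirs %*% moment) - u * mr
  rho <- sqrt(1 - 2 * f * u + f^2)
  gcub <- 1 / rho^3
  radial <- 2 * (u - f) * gcub + (1 / rho - 1) / f
  tangential <- 2 * gcub + ((rho + 1) / rho) / (1 - f * u + rho)
  (mr * radial + mc * tangential) / (4 * pi * sigma * R^2)
}

# TrialSet from an explicit channels x samples generator function applied
# per trial; reference tag "none" skips the common-average invariant.
makeTrialSet <- function(nTrials, nCh, fs, trialLength, gen,
                         reference = "none",
                         labels = sprintf("CH%02d", seq_len(nCh))) {
  n <- round(fs * trialLength)
  dat <- array(0, dim = c(nTrials, nCh, n))
  for (tr in seq_len(nTrials)) dat[tr, , ] <- gen(tr)
  new("TrialSet", data = dat, samplingRate = fs, trialLength = trialLength,
      reference = reference, layoutRef = labels)
}

# Small cohort specification for fast end-to-end tests.
tinySpec <- function(seed = 1L, ...) {
  args <- list(nPatients = 4L, nControls = 4L, nChannels = 32L,
               verticesPerHemisphere = 42L, nRegions = 8L, nNetworks = 4L,
               samplingRate = 150, recordingLength = 60, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohortSpec, args)
}

nullBandEffects <- c(delta = 1, theta = 1, alpha = 1, beta1 = 1, beta2 = 1,
                     gamma = 1)
nullCoupling <- c(delta = 0, theta = 0, alpha = 0, beta1 = 0, beta2 = 0,
                  gamma = 0)

# Covariate table of a set of subject records.
recordCovariates <- function(records) {
  data.frame(subject = vapply(records, function(r) r@id, character(1L)),
             group = vapply(records, function(r) r@group, character(1L)),
             age = vapply(records, function(r) r@age, numeric(1L)),
             sex = vapply(records, function(r) r@sex, integer(1L)),
             site = vapply(records, function(r) r@site, integer(1L)))
}

# Analytic sensor CSD for given per-source densities through a gain matrix.
analyticCsd <- function(G, densities, noise, band, labels) {
  C <- G %*% (densities * t(G)) + diag(noise, nrow(G))
  new("SensorCsd", matrix = C + 0i, band = band, dof = 1e6, labels = labels)
}
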