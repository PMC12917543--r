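#' @import methods
NULL

#' Three-shell spherical head geometry
#'
#' Concentric-sphere volume conductor with three compartments (brain, skull,
#' scalp). Radii are in metres and strictly increasing; conductivities are in
#' S/m. This is the analytic stand-in for a three-layer boundary element
#' model: it keeps the three-compartment physics (notably the resistive
#' skull) while admitting a closed-form series solution.
#'
#' @slot shellRadii numeric(3), outer radius of brain, skull and scalp shells (m).
#' @slot conductivities numeric(3), compartment conductivities (S/m).
#' @slot centre numeric(3), head centre in head coordinates (m).
#' @export
setClass("HeadGeometry",
  representation(shellRadii = "numeric", conductivities = "numeric",
                 centre = "numeric"),
  prototype(shellRadii = c(0.087, 0.092, 0.100),
            conductivities = c(0.33, 0.0066, 0.33),
            centre = c(0, 0, 0)))

setValidity("HeadGeometry", function(object) {
  msg <- character()
  if (length(object@shellRadii) != 3L) msg <- c(msg, "exactly 3 shell radii required")
  if (length(object@conductivities) != 3L) msg <- c(msg, "exactly 3 conductivities required")
  if (length(object@shellRadii) == 3L && any(diff(object@shellRadii) <= 0))
    msg <- c(msg, "shell radii must be strictly increasing (brain < skull < scalp)")
  if (any(object@conductivities <= 0)) msg <- c(msg, "conductivities must be positive")
  if (length(object@centre) != 3L) msg <- c(msg, "centre must be a 3-vector")
  if (length(msg)) msg else TRUE
})

#' Labelled electrode layout on the scalp sphere
#'
#' Channel positions on the scalp shell in head-centred Cartesian coordinates
#' (x right, y anterior, z superior). Channels snapped to the classical 10-20
#' anchor directions are flagged protected and survive every channel
#' reduction. Every off-midline channel is paired with its contralateral
#' mirror across the sagittal plane; midline channels pair with themselves.
#'
#' @slot labels character, unique channel names.
#' @slot positions numeric matrix (channels x 3), metres, on the scalp shell.
#' @slot protected character, labels of protected (10-20 anchor) channels.
#' @slot mirror named character, mirror partner label per channel (involution).
#' @slot scalpRadius numeric(1), scalp shell radius (m).
#' @export
setClass("ElectrodeLayout",
  representation(labels = "character", positions = "matrix",
                 protected = "character", mirror = "character",
                 scalpRadius = "numeric"))

setValidity("ElectrodeLayout", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (anyDuplicated(object@labels)) msg <- c(msg, "channel labels must be unique")
  if (nrow(object@positions) != n || ncol(object@positions) != 3L)
    msg <- c(msg, "positions must be a (channels x 3) matrix")
  r <- sqrt(rowSums(object@positions^2))
  if (n > 0 && any(abs(r - object@scalpRadius) > 1e-9 * object@scalpRadius))
    msg <- c(msg, "all positions must lie on the scalp shell")
  if (!all(object@protected %in% object@labels))
    msg <- c(msg, "protected must be a subset of labels")
  if (length(object@mirror) != n || !setequal(names(object@mirror), object@labels) ||
      !all(object@mirror %in% object@labels))
    msg <- c(msg, "mirror must map every label to a label")
  else if (!identical(unname(object@mirror[object@mirror[object@labels]]),
                      object@labels))
    msg <- c(msg, "mirror pairing must be an involution")
  if (length(msg)) msg else TRUE
})

#' Spherical cortical source space
#'
#' Two hemispheres, each a full geodesic icosphere of 10 k^2 + 2 vertices
#' (the registration sphere, as in surface-based registration), carrying a
#' region parcellation (anatomical-style, split across hemispheres) and a
#' network parcellation (spanning both hemispheres symmetrically). Anatomical
#' dipole positions compress each hemisphere sphere into its half of the head
#' and radiate at a constant cortical depth (0.85 x the brain radius), so
#' every source is equally resolvable from the scalp; registration
#' coordinates stay on the unit sphere and are what spin-test rotations act
#' on.
#'
#' @slot anatomical numeric matrix (vertices x 3), dipole positions relative
#'   to the head centre in brain-radius units (multiply by the brain shell
#'   radius to get metres); all at radius 0.85.
#' @slot sphere numeric matrix (vertices x 3), per-hemisphere registration
#'   coordinates on the unit sphere.
#' @slot hemi integer, 1 = left, 2 = right per vertex.
#' @slot region integer, region label per vertex (1..nRegions).
#' @slot network integer, network label per vertex (1..nNetworks).
#' @slot triangles integer matrix (faces x 3), 1-based vertex indices.
#' @slot nRegions integer(1).
#' @slot nNetworks integer(1).
#' @export
setClass("SourceSpace",
  representation(anatomical = "matrix", sphere = "matrix", hemi = "integer",
                 region = "integer", network = "integer", triangles = "matrix",
                 nRegions = "integer", nNetworks = "integer"))

setValidity("SourceSpace", function(object) {
  msg <- character()
  nv <- nrow(object@anatomical)
  if (nrow(object@sphere) != nv) msg <- c(msg, "sphere/anatomical vertex counts differ")
  if (length(object@hemi) != nv || !all(object@hemi %in% 1:2))
    msg <- c(msg, "hemi must assign every vertex to hemisphere 1 or 2")
  if (length(unique(object@hemi)) != 2L) msg <- c(msg, "two hemispheres required")
  if (length(object@region) != nv || any(is.na(object@region)))
    msg <- c(msg, "every vertex needs exactly one region label")
  if (length(object@network) != nv || any(is.na(object@network)))
    msg <- c(msg, "every vertex needs exactly one network label")
  if (ncol(object@triangles) != 3L || any(object@triangles < 1L) ||
      any(object@triangles > nv))
    msg <- c(msg, "triangles must index vertices")
  if (length(msg)) msg else TRUE
})

#' EEG leadfield (forward gain matrix)
#'
#' Linear gain from unit dipoles (3 Cartesian orientations per vertex) to
#' channel potentials, in V per A m. Columns are vertex-major:
#' (v1x, v1y, v1z, v2x, ...). When \code{referenced} is TRUE the common
#' average reference has been applied and every column sums to zero over
#' channels.
#'
#' @slot gain numeric matrix (channels x 3*vertices).
#' @slot referenced logical(1).
#' @slot labels character, channel labels (row order of \code{gain}).
#' @export
setClass("LeadField",
  representation(gain = "matrix", referenced = "logical", labels = "character"))

setValidity("LeadField", function(object) {
  msg <- character()
  if (!all(is.finite(object@gain))) msg <- c(msg, "gain entries must be finite")
  if (ncol(object@gain) %% 3L != 0L) msg <- c(msg, "gain must have 3 columns per vertex")
  if (length(object@labels) != nrow(object@gain))
    msg <- c(msg, "one label per gain row required")
  if (isTRUE(object@referenced)) {
    cs <- abs(colSums(object@gain))
    tol <- 1e-10 * max(abs(object@gain), 1e-300)
    if (any(cs > tol)) msg <- c(msg, "referenced leadfield columns must sum to zero")
  }
  if (length(msg)) msg else TRUE
})

#' Segmented, re-referenced sensor trials
#'
#' Cleaned sensor data after filtering, decimation and segmentation:
#' non-overlapping trials under a common average reference, ready for
#' multitaper spectral analysis.
#'
#' @slot data numeric array (trials x channels x samples), microvolts.
#' @slot samplingRate numeric(1), Hz.
#' @slot trialLength numeric(1), seconds.
#' @slot reference character(1), reference tag ("average").
#' @slot layoutRef character, channel labels (second array dimension).
#' @export
setClass("TrialSet",
  representation(data = "array", samplingRate = "numeric",
                 trialLength = "numeric", reference = "character",
                 layoutRef = "character"))

setValidity("TrialSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be trials x channels x samples")
  else {
    if (d[3L] != round(object@samplingRate * object@trialLength))
      msg <- c(msg, "samples must equal samplingRate * trialLength")
    if (length(object@layoutRef) != d[2L])
      msg <- c(msg, "layoutRef must name every channel")
    if (identical(object@reference, "average") && d[1L] > 0) {
      cm <- colSums(aperm(object@data, c(2L, 1L, 3L))) / d[2L]
      if (max(abs(cm)) > 1e-8) msg <- c(msg, "channel mean must be 0 at every sample")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Frequency band specification
#'
#' A band is a centre frequency f0 with half-bandwidth W (the multitaper
#' smoothing); the band occupies f0 +/- W. The default registry
#' (\code{\link{defaultBands}}) holds the six standard resting-state bands.
#'
#' @slot name character(1).
#' @slot f0 numeric(1), centre frequency, Hz.
#' @slot halfBandwidth numeric(1), smoothing half-width W, Hz.
#' @export
setClass("BandSpec",
  representation(name = "character", f0 = "numeric", halfBandwidth = "numeric"))

setValidity("BandSpec", function(object) {
  msg <- character()
  if (object@f0 <= 0) msg <- c(msg, "f0 must be positive")
  if (object@halfBandwidth <= 0) msg <- c(msg, "halfBandwidth must be positive")
  if (object@f0 - object@halfBandwidth < 0) msg <- c(msg, "f0 - W must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Sensor-level cross-spectral density
#'
#' Hermitian channels x channels CSD at one band's centre frequency,
#' estimated by DPSS multitapers and averaged over tapers and trials;
#' dof = 2 * trials * tapers.
#'
#' @slot matrix complex matrix (channels x channels), uV^2/Hz.
#' @slot band \linkS4class{BandSpec}.
#' @slot dof numeric(1), degrees of freedom of the estimate.
#' @slot labels character, channel labels.
#' @export
setClass("SensorCsd",
  representation(matrix = "matrix", band = "BandSpec", dof = "numeric",
                 labels = "character"))

setValidity("SensorCsd", function(object) {
  msg <- character()
  m <- object@matrix
  if (nrow(m) != ncol(m)) msg <- c(msg, "CSD must be square")
  else {
    if (max(abs(m - Conj(t(m)))) > 1e-10 * max(abs(m), 1e-300))
      msg <- c(msg, "CSD must be Hermitian")
    dg <- diag(m)
    if (any(Re(dg) < -1e-12 * max(abs(dg), 1e-300)) || any(abs(Im(dg)) > 1e-10 * max(abs(dg), 1e-300)))
      msg <- c(msg, "CSD diagonal must be real and non-negative")
  }
  if (length(object@labels) != nrow(m)) msg <- c(msg, "one label per channel required")
  if (length(msg)) msg else TRUE
})

#' DICS spatial filters
#'
#' Per-vertex unit-gain beamformer filters at a fixed (dominant-power)
#' orientation. Because the regularized inverse uses the real part of the
#' CSD, the scalar filters are real-valued.
#'
#' @slot weights numeric matrix (vertices x channels).
#' @slot orientations numeric matrix (vertices x 3), unit dipole orientations.
#' @slot lambda numeric(1), regularization fraction of mean sensor power.
#' @slot labels character, channel labels.
#' @export
setClass("SpatialFilters",
  representation(weights = "matrix", orientations = "matrix",
                 lambda = "numeric", labels = "character"))

setValidity("SpatialFilters", function(object) {
  msg <- character()
  if (nrow(object@orientations) != nrow(object@weights) ||
      ncol(object@orientations) != 3L)
    msg <- c(msg, "orientations must be (vertices x 3)")
  else {
    nrm <- sqrt(rowSums(object@orientations^2))
    if (any(abs(nrm - 1) > 1e-9)) msg <- c(msg, "orientations must be unit norm")
  }
  if (object@lambda < 0) msg <- c(msg, "lambda must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-vertex metric map
#'
#' One value per source vertex for a single subject, band and head model:
#' either beamformer power (arbitrary units proportional to uV^2) or
#' vertex-mean absolute imaginary coherency (unitless, in [0, 1]).
#'
#' @slot values numeric, one value per vertex.
#' @slot metric character(1), "power" or "connectivity".
#' @slot band character(1), band name.
#' @slot headModel character(1), "individual" or "canonical".
#' @slot subject character(1), subject identifier.
#' @export
setClass("VertexMetricMap",
  representation(values = "numeric", metric = "character", band = "character",
                 headModel = "character", subject = "character"),
  prototype(headModel = "canonical", subject = ""))

setValidity("VertexMetricMap", function(object) {
  msg <- character()
  if (!object@metric %in% c("power", "connectivity"))
    msg <- c(msg, "metric must be 'power' or 'connectivity'")
  if (identical(object@metric, "power") && any(object@values < 0))
    msg <- c(msg, "power values must be non-negative")
  if (identical(object@metric, "connectivity") &&
      (any(object@values < 0) || any(object@values > 1)))
    msg <- c(msg, "connectivity values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Parcel-aggregated metric map
#'
#' Vertex metrics averaged (unweighted) within each parcel of a parcellation
#' scheme.
#'
#' @slot values numeric, one value per parcel (ordered by label index).
#' @slot parcellation character(1), "regions", "networks" or "vertices".
#' @slot band character(1).
#' @slot metric character(1).
#' @export
setClass("ParcelMap",
  representation(values = "numeric", parcellation = "character",
                 band = "character", metric = "character"))

#' TFCE parameters
#'
#' Threshold-free cluster enhancement settings: extent exponent E, height
#' exponent H and integration step dh expressed as a fraction of the map
#' maximum. Defaults E = 1, H = 2, dh = 1/100 are the standard surface-data
#' recommendation.
#'
#' @slot E numeric(1), extent exponent.
#' @slot H numeric(1), height exponent.
#' @slot dh numeric(1), step as a fraction of the map maximum.
#' @export
setClass("TfceParams",
  representation(E = "numeric", H = "numeric", dh = "numeric"),
  prototype(E = 1, H = 2, dh = 0.01))

setValidity("TfceParams", function(object) {
  if (object@E > 0 && object@H > 0 && object@dh > 0) TRUE
  else "E, H and dh must all be positive"
})

#' Permutation GLM result
#'
#' Group-contrast statistics per unit (vertex, parcel or global scalar):
#' t values, Cohen d derived from them, TFCE-enhanced statistics and
#' FWE-corrected one-sided permutation p-values with their -log10 transform.
#'
#' @slot tMap numeric.
#' @slot dMap numeric, Cohen d = t * sqrt(1/n1 + 1/n2).
#' @slot tfceMap numeric, empty when TFCE was not applied.
#' @slot pFwe numeric, FWE-corrected (max-statistic) p per unit; plain
#'   permutation p for scalar input.
#' @slot neglog10P numeric, -log10(pFwe).
#' @slot nPermutations integer(1).
#' @slot seed integer(1).
#' @slot tfceParams \linkS4class{TfceParams}.
#' @slot n1 integer(1), patients.
#' @slot n2 integer(1), controls.
#' @export
setClass("StatResult",
  representation(tMap = "numeric", dMap = "numeric", tfceMap = "numeric",
                 pFwe = "numeric", neglog10P = "numeric",
                 nPermutations = "integer", seed = "integer",
                 tfceParams = "TfceParams", n1 = "integer", n2 = "integer"))

setValidity("StatResult", function(object) {
  msg <- character()
  if (any(object@pFwe <= 0) || any(object@pFwe > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (any(abs(object@neglog10P + log10(object@pFwe)) > 1e-12))
    msg <- c(msg, "neglog10P must equal -log10(pFwe)")
  if (length(msg)) msg else TRUE
})

#' Spin-test result
#'
#' Observed Spearman correlation between two cortical maps and its null
#' distribution under random per-hemisphere rotations of the registration
#' sphere (mirrored across hemispheres).
#'
#' @slot rObserved numeric(1).
#' @slot nullDistribution numeric, one rho per rotation.
#' @slot nRotations integer(1).
#' @slot pSpin numeric(1), two-sided plus-one permutation p.
#' @export
setClass("SpinResult",
  representation(rObserved = "numeric", nullDistribution = "numeric",
                 nRotations = "integer", pSpin = "numeric"))

setValidity("SpinResult", function(object) {
  p <- (1 + sum(abs(object@nullDistribution) >= abs(object@rObserved))) /
    (1 + object@nRotations)
  if (abs(p - object@pSpin) > 1e-12) "pSpin must follow the plus-one count formula"
  else if (object@pSpin <= 0 || object@pSpin > 1) "pSpin must lie in (0, 1]"
  else TRUE
})

#' Fisher-z comparison of two correlations
#'
#' Independent-samples z-difference test between two correlation coefficients
#' observed on n1 and n2 spatial units.
#'
#' @slot r1,r2 numeric(1), the two correlations.
#' @slot z1,z2 numeric(1), their Fisher-z transforms (atanh).
#' @slot n1,n2 numeric(1), spatial-unit counts.
#' @slot zDiff numeric(1), (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3)).
#' @slot p numeric(1), two-sided normal p.
#' @export
setClass("CorrelationComparison",
  representation(r1 = "numeric", r2 = "numeric", z1 = "numeric", z2 = "numeric",
                 n1 = "numeric", n2 = "numeric", zDiff = "numeric", p = "numeric"))

#' Synthetic cohort specification
#'
#' Generative settings for a seeded two-group resting-state EEG cohort with
#' known source-level effects. Defaults mirror the reference study design:
#' 35 patients vs 54 controls, 256 channels, group-elevated theta-band source
#' amplitude (ratio 1.4) in the active regions, additional 90-degrees-lagged
#' theta coupling (+0.3) between designated region pairs, per-subject head
#' geometry jitter (2 percent), two recording sites, and spike-wave-like
#' high-amplitude burst marks in about a third of patients.
#'
#' @slot nPatients,nControls integer(1), group sizes.
#' @slot nChannels integer(1), montage size of the simulated recording.
#' @slot verticesPerHemisphere integer(1), source-space resolution (10 k^2 + 2).
#' @slot nRegions,nNetworks integer(1), parcellation sizes.
#' @slot samplingRate numeric(1), raw sampling rate, Hz (integer multiple of 150).
#' @slot recordingLength numeric(1), seconds.
#' @slot bandEffects named numeric, patient/control source-amplitude ratio per band.
#' @slot couplingEffect named numeric, patient increment of lagged coupling per band.
#' @slot activeRegions integer, region labels carrying the effects.
#' @slot couplingPairs integer matrix (pairs x 2), coupled region labels.
#' @slot snr numeric(1), sensor-level signal-to-noise amplitude ratio.
#' @slot geometryJitter numeric(1), relative s.d. of per-subject shell-radius
#'   and electrode-position perturbation.
#' @slot nSites integer(1).
#' @slot ageMean,ageSd numeric(1), years.
#' @slot markRate numeric(1), fraction of patients with burst-marked trials.
#' @slot sourceMode character(1), "vertex" (independent source per cortical
#'   vertex) or "region" (one source per region centroid; coarse but cheap).
#' @slot seed integer(1).
#' @export
setClass("CohortSpec",
  representation(nPatients = "integer", nControls = "integer",
                 nChannels = "integer", verticesPerHemisphere = "integer",
                 nRegions = "integer", nNetworks = "integer",
                 samplingRate = "numeric", recordingLength = "numeric",
                 bandEffects = "numeric", couplingEffect = "numeric",
                 activeRegions = "integer", couplingPairs = "matrix",
                 snr = "numeric", geometryJitter = "numeric",
                 nSites = "integer", ageMean = "numeric", ageSd = "numeric",
                 markRate = "numeric", sourceMode = "character",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPatients < 1L || object@nControls < 1L)
    msg <- c(msg, "group counts must be positive")
  if (object@snr <= 0) msg <- c(msg, "snr must be positive")
  if (any(object@bandEffects < 0)) msg <- c(msg, "bandEffects must be >= 0")
  if (object@samplingRate %% 150 != 0)
    msg <- c(msg, "samplingRate must be an integer multiple of 150 Hz")
  if (length(msg)) msg else TRUE
})

#' One simulated subject
#'
#' @slot id character(1).
#' @slot group character(1), "patient" or "control".
#' @slot age numeric(1), years.
#' @slot sex integer(1), 0/1 code.
#' @slot site integer(1), site index.
#' @slot geometry \linkS4class{HeadGeometry}, the subject's true (jittered) shells.
#' @slot layout \linkS4class{ElectrodeLayout}, the subject's true electrode positions.
#' @slot sensorData numeric matrix (channels x samples), microvolts.
#' @slot samplingRate numeric(1), Hz.
#' @slot marks integer, 0-based indices of artefact/spike-wave-like trials.
#' @export
setClass("SubjectRecord",
  representation(id = "character", group = "character", age = "numeric",
                 sex = "integer", site = "integer", geometry = "HeadGeometry",
                 layout = "ElectrodeLayout", sensorData = "matrix",
                 samplingRate = "numeric", marks = "integer"))

setValidity("SubjectRecord", function(object) {
  msg <- character()
  if (!object@group %in% c("patient", "control"))
    msg <- c(msg, "group must be 'patient' or 'control'")
  if (!all(is.finite(object@sensorData))) msg <- c(msg, "sensor data must be finite")
  nTrials <- floor(ncol(object@sensorData) / object@samplingRate / 10)
  if (length(object@marks) && (any(object@marks < 0L) || any(object@marks >= nTrials)))
    msg <- c(msg, "marks must index trials within the recording")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' Expected direction of the patient-minus-control difference per vertex,
#' band and metric; nonzero only in the configured active regions (power)
#' and coupled region pairs (connectivity).
#'
#' @slot powerMaps named list of numeric vertex maps, one per band with an effect.
#' @slot connMaps named list of numeric vertex maps, one per band with coupling.
#' @slot activeRegions integer.
#' @slot couplingPairs integer matrix (pairs x 2).
#' @export
setClass("GroundTruth",
  representation(powerMaps = "list", connMaps = "list",
                 activeRegions = "integer", couplingPairs = "matrix"))

#' Pipeline run configuration
#'
#' Settings for a full simulated study: cohort, channel-set ladder (the
#' 256-channel set is the mandatory reference), bands, head-model modes,
#' parcellations, permutation and rotation counts.
#'
#' @slot cohort \linkS4class{CohortSpec}.
#' @slot channelSets integer, descending montage sizes; must contain the
#'   full montage (reference).
#' @slot bands list of \linkS4class{BandSpec}.
#' @slot headModels character, subset of c("individual", "canonical").
#' @slot parcellations character, subset of c("vertices", "regions", "networks").
#' @slot nTrialsSelect integer(1), clean trials drawn per subject.
#' @slot nPerm integer(1), permutations for group statistics.
#' @slot nRotations integer(1), spin-test rotations.
#' @slot seed integer(1).
#' @slot spinBand character(1), band whose effect-size maps enter the spatial
#'   comparisons.
#' @export
setClass("RunConfig",
  representation(cohort = "CohortSpec", channelSets = "integer",
                 bands = "list", headModels = "character",
                 parcellations = "character", nTrialsSelect = "integer",
                 nPerm = "integer", nRotations = "integer", seed = "integer",
                 spinBand = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@channelSets), strictly = TRUE))
    msg <- c(msg, "channel sets must be strictly descending")
  if (!object@cohort@nChannels %in% object@channelSets)
    msg <- c(msg, "the full montage must be present in channelSets as reference")
  if (!all(object@headModels %in% c("individual", "canonical")))
    msg <- c(msg, "headModels must be 'individual' and/or 'canonical'")
  if (!all(object@parcellations %in% c("vertices", "regions", "networks")))
    msg <- c(msg, "unknown parcellation")
  if (length(msg)) msg else TRUE
})
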