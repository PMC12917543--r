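#' @include AllGenerics.R
NULL

#' @describeIn nChannels channels in a layout
#' @export
setMethod("nChannels", "ElectrodeLayout", function(x) length(x@labels))
#' @describeIn nChannels rows of the gain matrix
#' @export
setMethod("nChannels", "LeadField", function(x) nrow(x@gain))
#' @describeIn nChannels second data dimension
#' @export
setMethod("nChannels", "TrialSet", function(x) dim(x@data)[2L])
#' @describeIn nChannels CSD dimension
#' @export
setMethod("nChannels", "SensorCsd", function(x) nrow(x@matrix))

#' @describeIn channelLabels layout labels
#' @export
setMethod("channelLabels", "ElectrodeLayout", function(x) x@labels)
#' @describeIn channelLabels leadfield row labels
#' @export
setMethod("channelLabels", "LeadField", function(x) x@labels)
#' @describeIn channelLabels trial channel labels
#' @export
setMethod("channelLabels", "TrialSet", function(x) x@layoutRef)
#' @describeIn channelLabels CSD channel labels
#' @export
setMethod("channelLabels", "SensorCsd", function(x) x@labels)

#' @describeIn nVertices vertices in a source space
#' @export
setMethod("nVertices", "SourceSpace", function(x) nrow(x@anatomical))
#' @describeIn nVertices vertices spanned by the gain matrix
#' @export
setMethod("nVertices", "LeadField", function(x) ncol(x@gain) %/% 3L)
#' @describeIn nVertices filter rows
#' @export
setMethod("nVertices", "SpatialFilters", function(x) nrow(x@weights))
#' @describeIn nVertices map length
#' @export
setMethod("nVertices", "VertexMetricMap", function(x) length(x@values))

#' @describeIn nTrials first data dimension
#' @export
setMethod("nTrials", "TrialSet", function(x) dim(x@data)[1L])

#' @describeIn protectedChannels labels of the 10-20 anchors
#' @export
setMethod("protectedChannels", "ElectrodeLayout", function(x) x@protected)

#' @describeIn channelPositions scalp positions in metres
#' @export
setMethod("channelPositions", "ElectrodeLayout", function(x) {
  p <- x@positions
  rownames(p) <- x@labels
  p
})

#' @describeIn mirrorPairs the involution over labels
#' @export
setMethod("mirrorPairs", "ElectrodeLayout", function(x) x@mirror)

#' @describeIn gainMatrix the gain matrix
#' @export
setMethod("gainMatrix", "LeadField", function(x) x@gain)

#' @describeIn isReferenced reference flag
#' @export
setMethod("isReferenced", "LeadField", function(x) x@referenced)

#' @describeIn metricValues per-vertex values
#' @export
setMethod("metricValues", "VertexMetricMap", function(x) x@values)
#' @describeIn metricValues per-parcel values
#' @export
setMethod("metricValues", "ParcelMap", function(x) x@values)

#' @describeIn meshEdges unique undirected edges of the triangulation
#' @export
setMethod("meshEdges", "SourceSpace", function(x) {
  tr <- x@triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
})

setMethod("show", "HeadGeometry", function(object) {
  cat("HeadGeometry: three concentric shells\n")
  cat(sprintf("  radii (m): %s\n", paste(format(object@shellRadii), collapse = " / ")))
  cat(sprintf("  conductivities (S/m): %s\n",
              paste(format(object@conductivities), collapse = " / ")))
})

setMethod("show", "ElectrodeLayout", function(object) {
  cat(sprintf("ElectrodeLayout: %d channels (%d protected 10-20 anchors), scalp radius %.3f m\n",
              nChannels(object), length(object@protected), object@scalpRadius))
})

setMethod("show", "SourceSpace", function(object) {
  cat(sprintf("SourceSpace: %d vertices (%d per hemisphere), %d regions, %d networks, %d triangles\n",
              nVertices(object), sum(object@hemi == 1L), object@nRegions,
              object@nNetworks, nrow(object@triangles)))
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d channels x %d vertices x 3 orientations (%s)\n",
              nChannels(object), nVertices(object),
              if (object@referenced) "average reference" else "unreferenced"))
})

setMethod("show", "TrialSet", function(object) {
  cat(sprintf("TrialSet: %d trials x %d channels x %d samples (%g Hz, %g s, %s reference)\n",
              nTrials(object), nChannels(object), dim(object@data)[3L],
              object@samplingRate, object@trialLength, object@reference))
})

setMethod("show", "BandSpec", function(object) {
  cat(sprintf("BandSpec: %s, %g +/- %g Hz\n", object@name, object@f0,
              object@halfBandwidth))
})

setMethod("show", "SensorCsd", function(object) {
  cat(sprintf("SensorCsd: %d x %d at %s (%g +/- %g Hz), dof = %g\n",
              nrow(object@matrix), ncol(object@matrix), object@band@name,
              object@band@f0, object@band@halfBandwidth, object@dof))
})

setMethod("show", "SpatialFilters", function(object) {
  cat(sprintf("SpatialFilters: %d vertices x %d channels (DICS, lambda = %g)\n",
              nrow(object@weights), ncol(object@weights), object@lambda))
})

setMethod("show", "VertexMetricMap", function(object) {
  cat(sprintf("VertexMetricMap: %s, band %s, %d vertices, head model %s\n",
              object@metric, object@band, length(object@values), object@headModel))
})

setMethod("show", "StatResult", function(object) {
  cat(sprintf("StatResult: %d units, %d permutations, %d vs %d subjects\n",
              length(object@tMap), object@nPermutations, object@n1, object@n2))
  cat(sprintf("  max |t| = %.3f, max d = %.3f, min FWE p = %.4g\n",
              max(abs(object@tMap)), max(object@dMap), min(object@pFwe)))
})

setMethod("show", "SpinResult", function(object) {
  cat(sprintf("SpinResult: rho = %.3f, p_spin = %.4g (%d rotations)\n",
              object@rObserved, object@pSpin, object@nRotations))
})

setMethod("show", "CorrelationComparison", function(object) {
  cat(sprintf("CorrelationComparison: z1 = %.3f (n=%g) vs z2 = %.3f (n=%g): z_diff = %.3f, p = %.4g\n",
              object@z1, object@n1, object@z2, object@n2, object@zDiff, object@p))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d patients vs %d controls, %d channels, %g s at %g Hz\n",
              object@nPatients, object@nControls, object@nChannels,
              object@recordingLength, object@samplingRate))
  eff <- object@bandEffects[object@bandEffects != 1]
  cat(sprintf("  band amplitude effects: %s; coupling: %s\n",
              if (length(eff)) paste(names(eff), eff, sep = "=", collapse = ", ") else "none",
              paste(names(object@couplingEffect[object@couplingEffect != 0]),
                    object@couplingEffect[object@couplingEffect != 0],
                    sep = "=", collapse = ", ")))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord %s: %s, age %.1f, sex %d, site %d, %d x %d samples, %d marked trials\n",
              object@id, object@group, object@age, object@sex, object@site,
              nrow(object@sensorData), ncol(object@sensorData), length(object@marks)))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: channel sets %s; %d bands; head models %s; parcellations %s\n",
              paste(object@channelSets, collapse = "/"), length(object@bands),
              paste(object@headModels, collapse = "+"),
              paste(object@parcellations, collapse = "+")))
})
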