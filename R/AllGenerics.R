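#' @include AllClasses.R
NULL

#' Number of channels
#' @param x an object with channels.
#' @return integer(1).
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Channel labels
#' @param x an object with channels.
#' @return character vector.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Number of source vertices
#' @param x an object with a source dimension.
#' @return integer(1).
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' Number of trials
#' @param x a \linkS4class{TrialSet}.
#' @return integer(1).
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Protected channel labels
#' @param x an \linkS4class{ElectrodeLayout}.
#' @return character vector of labels never removed by channel reduction.
#' @export
setGeneric("protectedChannels", function(x) standardGeneric("protectedChannels"))

#' Channel positions
#' @param x an \linkS4class{ElectrodeLayout}.
#' @return numeric matrix (channels x 3), metres.
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))

#' Mirror pairing of channels
#' @param x an \linkS4class{ElectrodeLayout}.
#' @return named character vector mapping each label to its sagittal mirror
#'   partner (midline channels map to themselves).
#' @export
setGeneric("mirrorPairs", function(x) standardGeneric("mirrorPairs"))

#' Forward gain matrix
#' @param x a \linkS4class{LeadField}.
#' @return numeric matrix (channels x 3*vertices), vertex-major columns.
#' @export
setGeneric("gainMatrix", function(x) standardGeneric("gainMatrix"))

#' Has the common average reference been applied?
#' @param x a \linkS4class{LeadField}.
#' @return logical(1).
#' @export
setGeneric("isReferenced", function(x) standardGeneric("isReferenced"))

#' Metric values
#' @param x a map or result object.
#' @return numeric vector of per-unit values.
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' Undirected mesh edges
#' @param x a \linkS4class{SourceSpace}.
#' @return integer matrix (edges x 2) of unique vertex index pairs.
#' @export
setGeneric("meshEdges", function(x) standardGeneric("meshEdges"))
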