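#' @include AllClasses.R
NULL

#' Aggregate a vertex map into parcels
#'
#' Unweighted mean of the vertex values within each region or network label;
#' parcel order follows the label index. The size-weighted mean of the
#' parcel values always equals the vertex global mean.
#'
#' @param map a \linkS4class{VertexMetricMap}.
#' @param sourceSpace the \linkS4class{SourceSpace} carrying the labels.
#' @param scheme "regions" or "networks".
#' @return a \linkS4class{ParcelMap}.
#' @examples
#' ss <- buildSourceSpace(42, nRegions = 4, nNetworks = 2, seed = 1)
#' m <- new("VertexMetricMap", values = rep(1, nVertices(ss)),
#'          metric = "power", band = "theta")
#' metricValues(aggregateMap(m, ss, "regions"))
#' @export
aggregateMap <- function(map, sourceSpace, scheme = c("regions", "networks")) {
  scheme <- match.arg(scheme)
  new("ParcelMap",
      values = aggregateValues(map@values, sourceSpace, scheme),
      parcellation = scheme, band = map@band, metric = map@metric)
}

# Parcel means for a bare numeric vertex vector (effect-size maps may be
# negative and so do not fit the VertexMetricMap value constraints).
aggregateValues <- function(values, sourceSpace, scheme) {
  lab <- if (scheme == "regions") sourceSpace@region else sourceSpace@network
  nP <- if (scheme == "regions") sourceSpace@nRegions else sourceSpace@nNetworks
  if (length(values) != length(lab))
    stop("map length does not match the source space")
  counts <- tabulate(lab, nbins = nP)
  if (any(counts == 0L))
    stop(sprintf("invalid parcellation: empty parcel in scheme '%s'", scheme))
  sums <- vapply(seq_len(nP), function(p) sum(values[lab == p]), numeric(1L))
  sums / counts
}
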