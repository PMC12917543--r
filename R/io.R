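#' @include AllClasses.R
NULL

#' Write / read an electrode layout
#'
#' Tab-separated table with one header line and columns label, x, y, z
#' (metres) and protected (0/1). Mirror pairing is reconstructed on read by
#' sagittal reflection (nearest channel to the mirrored position; midline
#' channels pair with themselves).
#'
#' @param layout an \linkS4class{ElectrodeLayout}.
#' @param path file path.
#' @return \code{readLayout} returns an \linkS4class{ElectrodeLayout}.
#' @export
writeLayout <- function(layout, path) {
  df <- data.frame(label = layout@labels, layout@positions,
                   protected = as.integer(layout@labels %in% layout@protected))
  names(df)[2:4] <- c("x", "y", "z")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLayout
#' @export
readLayout <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  dimnames(pos) <- NULL
  r <- mean(sqrt(rowSums(pos^2)))
  pos <- normalizeRows(pos) * r
  refl <- pos %*% diag(c(-1, 1, 1))
  mid <- abs(pos[, 1L]) < 1e-6 * r
  nn <- max.col(tcrossprod(refl, pos), ties.method = "first")
  mirror <- df$label[nn]
  mirror[mid] <- df$label[mid]
  names(mirror) <- df$label
  new("ElectrodeLayout", labels = df$label, positions = pos,
      protected = df$label[df$protected == 1L], mirror = mirror,
      scalpRadius = r)
}

#' Write / read a source space
#'
#' Two tab-separated tables: vertices (index, hemi, x, y, z, sx, sy, sz,
#' region, network; anatomical and registration-sphere coordinates; 0-based
#' indices) and triangles (v1, v2, v3; 0-based).
#'
#' @param sourceSpace a \linkS4class{SourceSpace}.
#' @param verticesPath,trianglesPath file paths.
#' @return \code{readSourceSpace} returns a \linkS4class{SourceSpace}.
#' @export
writeSourceSpace <- function(sourceSpace, verticesPath, trianglesPath) {
  v <- data.frame(index = seq_len(nVertices(sourceSpace)) - 1L,
                  hemi = sourceSpace@hemi, sourceSpace@anatomical,
                  sourceSpace@sphere, region = sourceSpace@region,
                  network = sourceSpace@network)
  names(v)[3:8] <- c("x", "y", "z", "sx", "sy", "sz")
  utils::write.table(v, verticesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- as.data.frame(sourceSpace@triangles - 1L)
  names(tr) <- c("v1", "v2", "v3")
  utils::write.table(tr, trianglesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(verticesPath)
}

#' @rdname writeSourceSpace
#' @export
readSourceSpace <- function(verticesPath, trianglesPath) {
  v <- utils::read.table(verticesPath, header = TRUE, sep = "\t")
  tr <- utils::read.table(trianglesPath, header = TRUE, sep = "\t")
  v <- v[order(v$index), ]
  new("SourceSpace",
      anatomical = unname(as.matrix(v[, c("x", "y", "z")])),
      sphere = unname(as.matrix(v[, c("sx", "sy", "sz")])),
      hemi = as.integer(v$hemi), region = as.integer(v$region),
      network = as.integer(v$network),
      triangles = unname(as.matrix(tr)) + 1L,
      nRegions = length(unique(v$region)),
      nNetworks = length(unique(v$network)))
}

# Minimal text array container: JSON with dims, named metadata and the
# flattened (column-major) data.
writeArrayContainer <- function(data, meta, path) {
  obj <- list(dims = dim(data), meta = meta, data = as.vector(data))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

readArrayContainer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arr <- array(obj$data, dim = obj$dims)
  list(data = arr, meta = obj$meta)
}

#' Write / read a leadfield
#'
#' Array-container file (JSON) with shape metadata (channels, vertices, 3),
#' channel labels and the referenced flag.
#'
#' @param leadfield a \linkS4class{LeadField}.
#' @param path file path.
#' @return \code{readLeadfield} returns a \linkS4class{LeadField}.
#' @export
writeLeadfield <- function(leadfield, path) {
  writeArrayContainer(leadfield@gain,
                      list(type = "leadfield", channels = nrow(leadfield@gain),
                           vertices = ncol(leadfield@gain) %/% 3L,
                           referenced = leadfield@referenced,
                           labels = leadfield@labels), path)
}

#' @rdname writeLeadfield
#' @export
readLeadfield <- function(path) {
  x <- readArrayContainer(path)
  new("LeadField", gain = x$data, referenced = isTRUE(x$meta$referenced),
      labels = as.character(x$meta$labels))
}

#' Write / read a trial set
#'
#' Array-container file (JSON) with shape (trials, channels, samples) and
#' metadata: sampling rate, trial length, reference tag and channel labels.
#'
#' @param trials a \linkS4class{TrialSet}.
#' @param path file path.
#' @return \code{readTrialSet} returns a \linkS4class{TrialSet}.
#' @export
writeTrialSet <- function(trials, path) {
  writeArrayContainer(trials@data,
                      list(type = "trialset", samplingRate = trials@samplingRate,
                           trialLength = trials@trialLength,
                           reference = trials@reference,
                           labels = trials@layoutRef), path)
}

#' @rdname writeTrialSet
#' @export
readTrialSet <- function(path) {
  x <- readArrayContainer(path)
  new("TrialSet", data = x$data, samplingRate = x$meta$samplingRate,
      trialLength = x$meta$trialLength, reference = x$meta$reference,
      layoutRef = as.character(x$meta$labels))
}

#' Export a metric map as a tab-separated table
#'
#' Columns vertex (0-based) and value, with metadata (metric, band, head
#' model, subject) in comment lines.
#'
#' @param map a \linkS4class{VertexMetricMap} or \linkS4class{ParcelMap}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeMetricMap <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is(map, "VertexMetricMap"))
    writeLines(sprintf("# metric=%s band=%s headModel=%s subject=%s",
                       map@metric, map@band, map@headModel, map@subject), con)
  else
    writeLines(sprintf("# metric=%s band=%s parcellation=%s",
                       map@metric, map@band, map@parcellation), con)
  unit <- if (is(map, "VertexMetricMap")) "vertex" else "parcel"
  writeLines(paste(unit, "value", sep = "\t"), con)
  writeLines(sprintf("%d\t%.17g", seq_along(map@values) - 1L, map@values), con)
  invisible(path)
}

#' Export permutation GLM results
#'
#' Tab-separated map table (unit, t, d, tfce, p_fwe, neglog10_p) preceded by
#' a run-metadata comment block (seed, permutations, TFCE parameters, group
#' sizes).
#'
#' @param result a \linkS4class{StatResult}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeStatResult <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# nPermutations=%d seed=%d n1=%d n2=%d",
                       result@nPermutations, result@seed, result@n1, result@n2),
               sprintf("# tfce E=%g H=%g dh=%g", result@tfceParams@E,
                       result@tfceParams@H, result@tfceParams@dh)), con)
  writeLines("unit\tt\td\ttfce\tp_fwe\tneglog10_p", con)
  tf <- if (length(result@tfceMap)) result@tfceMap else rep(NA_real_, length(result@tMap))
  writeLines(sprintf("%d\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g",
                     seq_along(result@tMap) - 1L, result@tMap,
                     as.numeric(result@dMap), tf, result@pFwe,
                     result@neglog10P), con)
  invisible(path)
}
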