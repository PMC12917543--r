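#' @include utils.R
NULL

# Geodesic tessellation of the icosahedron with linear division frequency k:
# each face splits into k^2 triangles, giving 10 k^2 + 2 unit-sphere vertices.
icosphere <- function(k) {
  t <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1, t, 0, 1, t, 0, -1, -t, 0, 1, -t, 0,
                0, -1, t, 0, 1, t, 0, -1, -t, 0, 1, -t,
                t, 0, -1, t, 0, 1, -t, 0, -1, -t, 0, 1),
              ncol = 3, byrow = TRUE)
  v <- normalizeRows(v)
  f <- matrix(c(0, 11, 5, 0, 5, 1, 0, 1, 7, 0, 7, 10, 0, 10, 11,
                1, 5, 9, 5, 11, 4, 11, 10, 2, 10, 7, 6, 7, 1, 8,
                3, 9, 4, 3, 4, 2, 3, 2, 6, 3, 6, 8, 3, 8, 9,
                4, 9, 5, 2, 4, 11, 6, 2, 10, 8, 6, 7, 9, 8, 1),
              ncol = 3, byrow = TRUE) + 1L

  verts <- list(); tris <- list(); keys <- new.env(hash = TRUE)
  nv <- 0L
  getIndex <- function(p) {
    p <- p / sqrt(sum(p^2))
    key <- paste(sprintf("%.9f", round(p, 9) + 0), collapse = ",")
    idx <- keys[[key]]
    if (is.null(idx)) {
      nv <<- nv + 1L
      verts[[nv]] <<- p
      keys[[key]] <- nv
      idx <- nv
    }
    idx
  }
  for (fi in seq_len(nrow(f))) {
    A <- v[f[fi, 1L], ]; B <- v[f[fi, 2L], ]; C <- v[f[fi, 3L], ]
    # barycentric grid indices for this face
    grid <- matrix(0L, k + 1L, k + 1L)
    for (i in 0:k) for (j in 0:(k - i))
      grid[i + 1L, j + 1L] <- getIndex((A * (k - i - j) + B * i + C * j) / k)
    for (i in 0:(k - 1L)) for (j in 0:(k - 1L - i)) {
      tris[[length(tris) + 1L]] <-
        c(grid[i + 1L, j + 1L], grid[i + 2L, j + 1L], grid[i + 1L, j + 2L])
      if (j < k - 1L - i)
        tris[[length(tris) + 1L]] <-
          c(grid[i + 2L, j + 1L], grid[i + 2L, j + 2L], grid[i + 1L, j + 2L])
    }
  }
  list(vertices = do.call(rbind, verts), triangles = do.call(rbind, tris))
}

# Mesh-graph Voronoi labelling: nearest seed vertex by weighted shortest path.
growPatches <- function(vertices, edges, seedVertices) {
  w <- sqrt(rowSums((vertices[edges[, 1L], , drop = FALSE] -
                     vertices[edges[, 2L], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  d <- igraph::distances(g, v = seedVertices, weights = w)
  apply(d, 2L, which.min)
}

#' Build a two-hemisphere spherical source space
#'
#' Each hemisphere is a geodesic icosphere (10 k^2 + 2 vertices; 162 for
#' k = 4, 1002 for k = 10 -- the standard-resolution registration meshes).
#' Region labels are grown as spatially contiguous mesh patches from
#' \code{nRegions/2} seed vertices per hemisphere (mirror-symmetric across
#' hemispheres); network labels are grown likewise from \code{nNetworks}
#' seeds and span both hemispheres symmetrically. Anatomical dipole
#' positions place each hemisphere sphere (scaled 0.42) at +/- 0.47 of the
#' brain radius along the left-right axis, so every dipole lies strictly
#' inside 0.9 x the brain compartment.
#'
#' @param verticesPerHemisphere vertices per hemisphere; must equal
#'   10 k^2 + 2 for integer k (e.g. 42, 162, 1002).
#' @param nRegions total region parcels (even, split across hemispheres).
#' @param nNetworks network parcels (shared across hemispheres).
#' @param seed integer seed for the parcel seeds.
#' @return a \linkS4class{SourceSpace}.
#' @examples
#' ss <- buildSourceSpace(162, nRegions = 68, nNetworks = 14, seed = 1)
#' nVertices(ss)
#' @export
buildSourceSpace <- function(verticesPerHemisphere = 1002L, nRegions = 68L,
                             nNetworks = 14L, seed = 1L) {
  k <- sqrt((verticesPerHemisphere - 2) / 10)
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("verticesPerHemisphere must be of the form 10*k^2 + 2 (e.g. 42, 162, 1002)")
  k <- as.integer(round(k))
  nRegions <- as.integer(nRegions); nNetworks <- as.integer(nNetworks)
  if (nRegions %% 2L != 0L) stop("nRegions must be even (split across hemispheres)")
  if (nRegions < 2L || nRegions / 2L > verticesPerHemisphere)
    stop("infeasible region count for this mesh resolution")
  if (nNetworks < 1L || nNetworks > verticesPerHemisphere)
    stop("infeasible network count for this mesh resolution")

  ico <- icosphere(k)
  V <- nrow(ico$vertices)
  stopifnot(V == verticesPerHemisphere)
  regLeft <- ico$vertices
  regRight <- regLeft * rep(c(-1, 1, 1), each = V)  # mirror twin per index
  # anatomical mapping: compress each registration sphere into its half-space
  # (left: x <= 0) and radiate at a constant cortical depth of 0.85 x brain
  # radius; constant depth keeps every source equally resolvable by scalp
  # sensors and the mapping is injective and mirror-symmetric
  squash <- function(reg, sgn) {
    d <- cbind(sgn * (0.45 * sgn * reg[, 1L] - 0.55), reg[, 2L], reg[, 3L])
    0.85 * normalizeRows(d)
  }
  anat <- rbind(squash(regLeft, 1), squash(regRight, -1))
  tris <- rbind(ico$triangles, ico$triangles + V)

  edges1 <- unique(rbind(ico$triangles[, 1:2], ico$triangles[, 2:3],
                         ico$triangles[, c(1L, 3L)]))
  nR2 <- nRegions %/% 2L
  regionSeeds <- withSeed(deriveSeed(seed, 101L), sample.int(V, nR2))
  networkSeeds <- withSeed(deriveSeed(seed, 202L), sample.int(V, nNetworks))
  regLab1 <- growPatches(regLeft, edges1, regionSeeds)
  netLab1 <- growPatches(regLeft, edges1, networkSeeds)

  new("SourceSpace",
      anatomical = anat,
      sphere = rbind(regLeft, regRight),
      hemi = rep(1:2, each = V),
      region = as.integer(c(regLab1, regLab1 + nR2)),
      network = as.integer(rep(netLab1, 2L)),
      triangles = tris,
      nRegions = nRegions, nNetworks = nNetworks)
}
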