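# Shared fixture: referenced leadfield over a small head for beamformer tests.
dicsFixture <- function() {
  if (is.null(.fix$dics)) {
    lay <- fixLayout(64L, seed = 1L)
    ss <- fixSourceSpace(162L, 68L, 14L)
    lf <- averageReference(computeLeadfield(lay, ss, fixGeometry()))
    .fix$dics <- list(lay = lay, ss = ss, lf = lf)
  }
  .fix$dics
}

orientedColumn <- function(lf, v, u) {
  gainMatrix(lf)[, (3 * v - 2):(3 * v)] %*% u
}

test_that("unit-gain constraint holds at every vertex", {
  fx <- dicsFixture()
  set.seed(21)
  C <- crossprod(matrix(rnorm(200 * 64), 200, 64)) / 200
  csd <- new("SensorCsd", matrix = C + 0i, band = defaultBands()$theta,
             dof = 400, labels = channelLabels(fx$lay))
  fl <- computeDicsFilters(csd, fx$lf, 0.05)
  gains <- vapply(seq_len(nVertices(fl)), function(v)
    sum(fl@weights[v, ] * orientedColumn(fx$lf, v, fl@orientations[v, ])),
    numeric(1L))
  expect_lt(max(abs(gains - 1)), 1e-8)
  expect_equal(sqrt(rowSums(fl@orientations^2)), rep(1, nVertices(fl)),
               tolerance = 1e-9)
  expect_error(computeDicsFilters(csd, computeLeadfield(fx$lay, fx$ss, fixGeometry())),
               "referenced")
})

test_that("noiseless single dipoles are localized at their vertex", {
  fx <- dicsFixture()
  ed <- meshEdges(fx$ss)
  set.seed(22)
  hits <- 0L
  for (i in 1:8) {
    v <- sample.int(nVertices(fx$ss), 1L)
    vd <- fx$ss@anatomical[v, ] / sqrt(sum(fx$ss@anatomical[v, ]^2))
    m <- rnorm(3); m <- m - sum(m * vd) * vd          # tangential moment
    m <- m / sqrt(sum(m^2)) * 1e-8
    l <- orientedColumn(fx$lf, v, m / 1e-8) * 1e-8
    csd <- new("SensorCsd", matrix = tcrossprod(l) + 0i,
               band = defaultBands()$theta, dof = 100,
               labels = channelLabels(fx$lay))
    fl <- computeDicsFilters(csd, fx$lf, 0.05)
    pk <- which.max(metricValues(computeSourcePower(fl, csd)))
    nbr <- unique(c(v, ed[ed[, 1L] == v, 2L], ed[ed[, 2L] == v, 1L]))
    hits <- hits + (pk %in% nbr)
  }
  expect_gte(hits, 7L)
})

test_that("source power follows the quadratic form", {
  fx <- dicsFixture()
  set.seed(23)
  C <- crossprod(matrix(rnorm(150 * 64), 150, 64)) / 150
  csd <- new("SensorCsd", matrix = C + 0i, band = defaultBands()$theta,
             dof = 300, labels = channelLabels(fx$lay))
  fl <- computeDicsFilters(csd, fx$lf, 0.05)
  # identity CSD: power equals the squared filter norm
  eye <- new("SensorCsd", matrix = diag(64) + 0i, band = defaultBands()$theta,
             dof = 300, labels = channelLabels(fx$lay))
  expect_equal(metricValues(computeSourcePower(fl, eye)),
               rowSums(fl@weights^2), tolerance = 1e-12)
  # zero CSD and scaling
  zero <- new("SensorCsd", matrix = matrix(0 + 0i, 64, 64),
              band = defaultBands()$theta, dof = 300,
              labels = channelLabels(fx$lay))
  expect_equal(metricValues(computeSourcePower(fl, zero)), rep(0, 324))
  four <- new("SensorCsd", matrix = 4 * C + 0i, band = defaultBands()$theta,
              dof = 300, labels = channelLabels(fx$lay))
  expect_equal(metricValues(computeSourcePower(fl, four)),
               4 * metricValues(computeSourcePower(fl, csd)), tolerance = 1e-12)
})

test_that("zero-lag mixtures yield vanishing imaginary coherency", {
  fx <- dicsFixture()
  set.seed(24)
  # one common signal instantaneously mixed into all channels, plus noise
  mix <- rnorm(64)
  C <- tcrossprod(mix) + diag(0.01, 64)     # real CSD: no lags anywhere
  csd <- new("SensorCsd", matrix = C + 0i, band = defaultBands()$theta,
             dof = 500, labels = channelLabels(fx$lay))
  fl <- computeDicsFilters(csd, fx$lf, 0.05)
  conn <- computeSourceConnectivity(fl, csd)
  expect_lt(max(conn$matrix), 1e-6)
  expect_equal(diag(conn$matrix), rep(0, 324))
  expect_equal(conn$matrix, t(conn$matrix))
})

test_that("a 90-degree lagged source pair stands out of the connectivity map", {
  fx <- dicsFixture()
  v1 <- 40L; v2 <- 250L
  u1 <- fx$ss@sphere[v1, ]; u2 <- fx$ss@sphere[v2, ]
  l1 <- orientedColumn(fx$lf, v1, u1); l2 <- orientedColumn(fx$lf, v2, u2)
  L <- cbind(l1, l2)
  S <- matrix(c(1, -0.8i, 0.8i, 1), 2, 2)   # Hermitian, 90-degree lag
  C <- L %*% S %*% Conj(t(L)) + diag(1e-4 * mean(Mod(diag(L %*% Conj(t(L))))), 64)
  csd <- new("SensorCsd", matrix = C, band = defaultBands()$theta,
             dof = 500, labels = channelLabels(fx$lay))
  fl <- computeDicsFilters(csd, fx$lf, 0.05)
  conn <- computeSourceConnectivity(fl, csd)
  expect_gt(conn$matrix[v1, v2], stats::median(conn$matrix))
  expect_true(all(conn$matrix >= 0 & conn$matrix <= 1))
})

test_that("metrics are invariant to common-mode sensor signals", {
  fx <- dicsFixture()
  set.seed(25)
  C <- crossprod(matrix(rnorm(150 * 64), 150, 64)) / 150 + 0i
  common <- complex(real = rnorm(1), imaginary = rnorm(1))
  v <- complex(real = rnorm(64), imaginary = rnorm(64)) * 0.05
  Cc <- C + outer(rep(1, 64), Conj(v)) + outer(v, rep(1, 64)) +
    Mod(common)^2 * matrix(1, 64, 64)
  lab <- channelLabels(fx$lay)
  mk <- function(M) new("SensorCsd",
                        matrix = (M + Conj(t(M))) / 2,
                        band = defaultBands()$theta, dof = 300, labels = lab)
  # common average re-referencing (the subset projection with all channels)
  c1 <- subsetCsd(mk(C), lab)
  c2 <- subsetCsd(mk(Cc), lab)
  f1 <- computeDicsFilters(c1, fx$lf, 0.05)
  f2 <- computeDicsFilters(c2, fx$lf, 0.05)
  p1 <- metricValues(computeSourcePower(f1, c1))
  p2 <- metricValues(computeSourcePower(f2, c2))
  expect_equal(p1, p2, tolerance = 1e-8)
  m1 <- computeSourceConnectivity(f1, c1)$map
  m2 <- computeSourceConnectivity(f2, c2)$map
  expect_equal(metricValues(m1), metricValues(m2), tolerance = 1e-8)
})

test_that("global mean reduces maps as expected", {
  m <- new("VertexMetricMap", values = c(0, 1), metric = "connectivity",
           band = "theta")
  expect_equal(globalMean(m), 0.5)
  const <- new("VertexMetricMap", values = rep(3.2, 10), metric = "power",
               band = "alpha")
  expect_equal(globalMean(const), 3.2)
  set.seed(26)
  v <- runif(101)
  rm <- new("VertexMetricMap", values = v, metric = "power", band = "delta")
  expect_equal(globalMean(rm), sum(v) / 101)
  expect_error(globalMean(new("VertexMetricMap", values = numeric(0),
                              metric = "power", band = "x")), "empty")
})
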