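test_that("spearman correlation handles ties like hand-averaged ranks", {
  a <- c(1, 2, 2, 4)
  b <- c(10, 20, 30, 40)
  ra <- c(1, 2.5, 2.5, 4)
  expect_equal(spearmanRank(a, b), stats::cor(ra, 1:4))
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearmanRank(x, x), 1)
  expect_equal(spearmanRank(x, rev(x) * 0 - seq_along(x)),
               spearmanRank(x, -seq_along(x)))
  expect_equal(spearmanRank(sort(x), rev(sort(x))), -1)
  expect_error(spearmanRank(rep(1, 5), x), "constant")
  expect_error(spearmanRank(1:4, 1:5), "equal length")
  expect_error(spearmanRank(1:2, 2:1), "at least 3")
})

test_that("Fisher z is the odd increasing atanh with its worked values", {
  expect_equal(fisherZ(0), 0)
  expect_equal(round(fisherZ(0.50), 2), 0.55)
  expect_equal(round(fisherZ(0.77), 2), 1.02)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_true(all(diff(fisherZ(r)) > 0))
  z <- seq(-3, 3, by = 0.25)
  expect_equal(fisherZ(tanh(z)), z, tolerance = 1e-12)
  expect_error(fisherZ(1), "< 1")
})

test_that("correlation comparison follows the z-difference formula", {
  eq <- compareCorrelations(0.8, 2004, 0.8, 68)
  expect_equal(eq@zDiff, 0)
  expect_equal(eq@p, 1)
  cmp <- compareCorrelations(0.6, 100, 0.2, 100)
  want <- (atanh(0.6) - atanh(0.2)) / sqrt(2 / 97)
  expect_equal(cmp@zDiff, want)
  expect_equal(cmp@p, 2 * pnorm(-abs(want)))
  expect_error(compareCorrelations(0.5, 3, 0.2, 100), "exceed 3")
})

test_that("spin test recovers identity and respects the plus-one floor", {
  ss <- fixSourceSpace(42L, 8L, 4L, seed = 2L)
  set.seed(12)
  m <- rnorm(nVertices(ss))
  sp <- spinTest(m, m, ss, nRotations = 199L, seed = 1L)
  expect_equal(sp@rObserved, 1)
  expect_gte(sp@pSpin, 1 / 200)
  expect_lte(sp@pSpin, 0.05)
  expect_length(sp@nullDistribution, 199L)
  # null rotations shuffle values without inventing new ones
  expect_error(spinTest(m[1:10], m, ss, 199L), "vertex-level")
  expect_error(spinTest(m, m, ss, 50L), "99")
  # observed rho invariant under a joint relabelling of both maps
  p <- sample(nVertices(ss))
  m2 <- rnorm(nVertices(ss))
  expect_equal(spearmanRank(m[p], m2[p]), spearmanRank(m, m2))
})

test_that("spin null p-values are roughly uniform for independent smooth maps", {
  ss <- fixSourceSpace(42L, 8L, 4L, seed = 2L)
  ed <- meshEdges(ss)
  A <- diag(nVertices(ss))
  for (k in seq_len(nrow(ed))) {
    A[ed[k, 1L], ed[k, 2L]] <- 1
    A[ed[k, 2L], ed[k, 1L]] <- 1
  }
  A <- A / rowSums(A)
  smoothMap <- function() {
    x <- rnorm(nVertices(ss))
    for (i in 1:4) x <- as.vector(A %*% x)
    x
  }
  set.seed(13)
  ps <- vapply(1:120, function(i)
    spinTest(smoothMap(), smoothMap(), ss, nRotations = 99L, seed = i)@pSpin,
    numeric(1L))
  # p-values live on the discrete plus-one grid; ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
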