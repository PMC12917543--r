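smallCov <- function(n) {
  set.seed(100 + n)
  data.frame(group = rep(c("patient", "control"), each = n / 2),
             age = round(rnorm(n, 30, 8)),
             sex = rep(c(0L, 1L), n / 2),
             site = rep(1L, n))
}

test_that("exhaustive permutation p matches an independent enumeration oracle", {
  cov <- smallCov(6L)
  set.seed(7)
  y <- rnorm(6) + 0.8 * (cov$group == "patient")
  des <- buildDesign(cov)
  expect_warning(res <- permutationGlm(y, des, nPerm = 720L, seed = 1L),
                 "capped")
  expect_equal(res@nPermutations, 720L)
  expect_equal(res@pFwe, freedmanLaneOracle(y, cov), tolerance = 1e-12)
})

test_that("flat maps give p = 1 and permuting subjects jointly changes nothing", {
  cov <- smallCov(6L)
  des <- buildDesign(cov)
  flat <- matrix(5, 6, 3)
  expect_warning(res <- permutationGlm(flat, des, nPerm = 720L, seed = 1L))
  expect_equal(res@pFwe, rep(1, 3))
  expect_equal(res@tMap, rep(0, 3))
  # exchangeability: reordering subjects identically in data and design
  set.seed(8)
  y <- rnorm(6)
  ord <- sample(6)
  des2 <- buildDesign(cov[ord, ])
  expect_warning(r1 <- permutationGlm(y, des, nPerm = 720L, seed = 1L))
  expect_warning(r2 <- permutationGlm(y[ord], des2, nPerm = 720L, seed = 1L))
  expect_equal(r1@tMap, r2@tMap, tolerance = 1e-12)
  # exhaustive permutation sets coincide; floating-point ties at the
  # boundary may shift the count by a permutation or two
  expect_equal(r1@pFwe, r2@pFwe, tolerance = 5e-3)
})

test_that("rank-deficient designs and misaligned maps are rejected", {
  cov <- smallCov(6L)
  cov$age <- 5
  expect_error(buildDesign(cov), "rank")
  des <- buildDesign(smallCov(6L))
  expect_error(permutationGlm(rnorm(5), des, nPerm = 99L), "align")
  expect_error(permutationGlm(rnorm(6), des, nPerm = 50L), "99")
})

test_that("TFCE matches the brute-force threshold-sum oracle", {
  # the 5-vertex path-graph worked example
  edges <- cbind(1:4, 2:5)
  v <- c(0, 1, 2, 1, 0)
  params <- new("TfceParams", E = 1, H = 2, dh = 0.01)
  expect_equal(tfceTransform(v, edges, params),
               tfceOracle(v, edges, 1, 2, 0.01), tolerance = 1e-9)
  # random small meshes with positive and negative values
  set.seed(9)
  for (i in 1:4) {
    n <- 12L
    edges <- unique(t(apply(cbind(sample(n, 20, TRUE), sample(n, 20, TRUE)),
                            1L, sort)))
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
    v <- rnorm(n)
    expect_equal(tfceTransform(v, edges, params),
                 tfceOracle(v, edges, 1, 2, 0.01), tolerance = 1e-9)
  }
  expect_equal(tfceTransform(rep(0, 5), cbind(1:4, 2:5), params), rep(0, 5))
})

test_that("TFCE is monotone in the input map", {
  set.seed(10)
  edges <- cbind(1:9, 2:10)
  params <- new("TfceParams")
  v <- abs(rnorm(10))
  base <- tfceTransform(v, edges, params)
  # raise vertices without touching the map maximum (the integration step
  # is defined relative to the maximum, so the ladder stays fixed)
  for (j in setdiff(c(2L, 7L), which.max(v))) {
    v2 <- v
    v2[j] <- (v2[j] + max(v)) / 2
    expect_true(all(tfceTransform(v2, edges, params) >= base - 1e-12))
  }
})

test_that("FWE control under the null holds at map level", {
  cov <- smallCov(12L)
  des <- buildDesign(cov)
  edges <- cbind(1:19, 2:20)
  params <- new("TfceParams")
  set.seed(11)
  any_sig <- vapply(1:40, function(i) {
    Y <- matrix(rnorm(12 * 20), 12, 20)
    res <- permutationGlm(Y, des, nPerm = 99L, seed = i, tfce = params,
                          edges = edges)
    any(res@pFwe <= 0.05)
  }, logical(1L))
  expect_lte(mean(any_sig), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 40) + 1e-9)
})

test_that("Cohen d conversion and interpretation metadata", {
  expect_equal(as.numeric(cohenDFromT(0, 10, 12)), 0)
  expect_equal(as.numeric(cohenDFromT(2, 20, 20)), 2 * sqrt(0.1))
  expect_equal(attr(cohenDFromT(1, 5, 5), "interpretation"),
               c(large = 0.8, medium = 0.5, small = 0.2))
  expect_error(cohenDFromT(1, 1, 10), "at least 2")
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(fdrBH(0.03)$q, 0.03)
  r <- fdrBH(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$q, rep(0.04, 4))
  expect_true(all(r$significant))
  same <- fdrBH(rep(0.2, 5))
  expect_equal(same$q, rep(0.2, 5))
  expect_false(any(same$significant))
  expect_error(fdrBH(c(0.1, 0)), "0, 1")
})

test_that("balance tests reproduce the chi-square and ANOVA conventions", {
  mkcov <- function(fp, mp, fc, mc) data.frame(
    group = c(rep("patient", fp + mp), rep("control", fc + mc)),
    sex = c(rep(1, fp), rep(0, mp), rep(1, fc), rep(0, mc)),
    age = c(seq_len(fp + mp) %% 13 + 24, seq_len(fc + mc) %% 11 + 26))
  b <- balanceTests(mkcov(35, 36, 26, 17))
  expect_equal(round(b$chiSquareSex, 2), 0.93)
  b2 <- balanceTests(mkcov(18, 17, 27, 27))
  expect_equal(round(b2$chiSquareSex, 2), 0)
  # identical proportions give exactly zero
  b3 <- balanceTests(mkcov(10, 10, 20, 20))
  expect_equal(b3$chiSquareSex, 0)
  # ANOVA F agrees with the base aov computation
  cov <- mkcov(10, 10, 12, 8)
  expect_equal(b <- balanceTests(cov)$Fage,
               summary(stats::aov(age ~ group, cov))[[1]][["F value"]][1])
  cov$sex <- 1
  expect_error(balanceTests(cov), "degenerate")
})
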