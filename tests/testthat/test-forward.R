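test_that("three-shell series reduces to the homogeneous closed form", {
  g <- new("HeadGeometry", shellRadii = c(0.087, 0.092, 0.1),
           conductivities = c(0.33, 0.33, 0.33))
  set.seed(11)
  edirs <- matrix(rnorm(30), 10, 3)
  edirs <- edirs / sqrt(rowSums(edirs^2))
  for (i in 1:4) {
    pos <- rnorm(3)
    pos <- pos / sqrt(sum(pos^2)) * runif(1, 0.005, 0.078)
    mom <- rnorm(3) * 1e-8
    got <- eegdens:::dipolePotential(edirs, pos, mom, g, nTerms = 300)
    want <- homogeneousSpherePotential(edirs, pos, mom, 0.33, 0.1)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
  }
})

test_that("forward solution is mirror-symmetric and linear in the moment", {
  g <- fixGeometry()
  set.seed(12)
  edirs <- matrix(rnorm(24), 8, 3)
  edirs <- edirs / sqrt(rowSums(edirs^2))
  pos <- c(0.03, 0.02, 0.04)
  mom <- c(1, 2, 3) * 1e-8
  M <- diag(c(-1, 1, 1))
  a <- eegdens:::dipolePotential(edirs, pos, mom, g, 120)
  b <- eegdens:::dipolePotential(edirs %*% M, as.vector(M %*% pos),
                                 as.vector(M %*% mom), g, 120)
  expect_lt(max(abs(a - b)), 1e-9 * max(abs(a)))
  # zero moment, superposition
  expect_equal(eegdens:::dipolePotential(edirs, pos, c(0, 0, 0), g), rep(0, 8))
  m1 <- c(1, 0, -2) * 1e-8; m2 <- c(0, 3, 1) * 1e-8
  lhs <- eegdens:::dipolePotential(edirs, pos, 2 * m1 + 0.5 * m2, g)
  rhs <- 2 * eegdens:::dipolePotential(edirs, pos, m1, g) +
    0.5 * eegdens:::dipolePotential(edirs, pos, m2, g)
  expect_lt(max(abs(lhs - rhs)), 1e-12 * max(abs(lhs)))
})

test_that("gain matrix agrees with direct dipole evaluation", {
  lay <- fixLayout(24L, seed = 1L)
  ss <- fixSourceSpace(42L, 4L, 2L)
  g <- fixGeometry()
  lf <- computeLeadfield(lay, ss, g, nTerms = 80L)
  expect_equal(dim(gainMatrix(lf)), c(24L, 3L * 84L))
  v <- 17L
  mom <- c(2, -1, 0.5) * 1e-8
  pred <- gainMatrix(lf)[, (3 * v - 2):(3 * v)] %*% mom
  dirs <- channelPositions(lay) / sqrt(rowSums(channelPositions(lay)^2))
  direct <- eegdens:::dipolePotential(dirs, ss@anatomical[v, ] * g@shellRadii[1L],
                                      mom, g, 80L)
  expect_lt(max(abs(pred - direct)), 1e-12 * max(abs(direct)))
  expect_error(computeLeadfield(lay, ss, g, nTerms = 10L), "nTerms")
})

test_that("average reference zeroes column sums, constants, and is idempotent", {
  lay <- fixLayout(24L, seed = 1L)
  ss <- fixSourceSpace(42L, 4L, 2L)
  lf <- computeLeadfield(lay, ss, fixGeometry())
  ref <- averageReference(lf)
  expect_true(isReferenced(ref))
  expect_lt(max(abs(colSums(gainMatrix(ref)))),
            1e-10 * max(abs(gainMatrix(ref))))
  expect_equal(gainMatrix(averageReference(ref)), gainMatrix(ref))
  const <- new("LeadField", gain = matrix(3.7, 5, 3), referenced = FALSE,
               labels = sprintf("C%d", 1:5))
  expect_equal(gainMatrix(averageReference(const)), matrix(0, 5, 3))
})
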