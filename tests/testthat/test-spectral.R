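test_that("default band registry matches the six standard bands", {
  b <- defaultBands()
  expect_named(b, c("delta", "theta", "alpha", "beta1", "beta2", "gamma"))
  f0 <- vapply(b, function(x) x@f0, numeric(1L))
  W <- vapply(b, function(x) x@halfBandwidth, numeric(1L))
  expect_equal(unname(f0), c(2, 6, 10, 16, 25, 40))
  expect_equal(unname(W), c(2, 2, 2, 4, 4, 8))
  expect_equal(taperCount(10, 2), 39L)
  expect_equal(taperCount(10, 4), 79L)
})

test_that("DPSS tapers are orthonormal and spectrally concentrated", {
  tp <- dpssTapers(512L, 8 / 512, 5L)
  expect_equal(crossprod(tp), diag(5), tolerance = 1e-10)
  # leading taper keeps almost all energy inside the half-bandwidth
  f <- stats::fft(c(tp[, 1L], rep(0, 7680)))
  p <- Mod(f)^2
  inside <- sum(p[1:129]) + sum(p[(8192 - 127):8192])  # |f| <= w
  expect_gt(inside / sum(p), 0.999)
})

test_that("a common sinusoid yields a rank-1 band CSD", {
  fs <- 150; n <- 1500
  t <- (0:(n - 1)) / fs
  gains <- c(0.5, 1, 1.5, 2, 3)
  ts <- makeTrialSet(3L, 5L, fs, 10, function(tr)
    outer(gains, sin(2 * pi * 10 * t + tr)))
  csd <- computeBandCsd(ts, defaultBands()$alpha)
  ev <- eigen(csd@matrix)$values
  expect_lt(Mod(ev[2L]) / Mod(ev[1L]), 1e-6)
  expect_equal(csd@dof, 2 * 3 * 39)
  # Hermitian PSD structure
  expect_lt(max(Mod(csd@matrix - Conj(t(csd@matrix)))), 1e-10 * max(Mod(csd@matrix)))
  expect_true(all(Re(diag(csd@matrix)) >= 0))
  expect_error(computeBandCsd(ts, new("BandSpec", name = "hf", f0 = 80,
                                      halfBandwidth = 4)), "Nyquist")
})

test_that("independent channels decorrelate as the dof grows", {
  fs <- 100; Tlen <- 5
  set.seed(33)
  ts <- makeTrialSet(31L, 6L, fs, Tlen, function(tr)
    matrix(rnorm(6 * fs * Tlen), 6))
  band <- new("BandSpec", name = "b", f0 = 20, halfBandwidth = 4)
  csd <- computeBandCsd(ts, band)          # dof = 2 * 31 * 39 = 2418
  expect_gte(csd@dof, 2400)
  coh <- Mod(csd@matrix) / sqrt(outer(Re(diag(csd@matrix)),
                                      Re(diag(csd@matrix))))
  expect_lt(mean(coh[upper.tri(coh)]), 0.05)
})

test_that("CSD subsetting equals re-referencing the subset channels", {
  spec <- tinySpec(seed = 2L)
  rec <- simulateSubject(spec, 1L)
  trials <- preprocessRecording(rec)
  band <- defaultBands()$theta
  keep <- channelLabels(trials)[c(2, 5, 9, 12, 20, 31)]
  sub <- subsetCsd(computeBandCsd(trials, band), keep)
  # oracle: subset the trial data, re-reference, recompute the CSD
  idx <- match(keep, trials@layoutRef)
  dat <- trials@data[, idx, , drop = FALSE]
  for (tr in seq_len(dim(dat)[1L]))
    dat[tr, , ] <- sweep(dat[tr, , ], 2L, colMeans(dat[tr, , ]))
  direct <- computeBandCsd(new("TrialSet", data = dat,
                               samplingRate = trials@samplingRate,
                               trialLength = trials@trialLength,
                               reference = "average", layoutRef = keep), band)
  expect_equal(sub@matrix, direct@matrix, tolerance = 1e-10)
  expect_error(subsetCsd(computeBandCsd(trials, band), c("nope")), "unknown")
})
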