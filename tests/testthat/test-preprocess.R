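test_that("segmentation arithmetic and referencing follow the contract", {
  set.seed(1)
  x <- matrix(rnorm(4 * 310 * 600), 4, 310 * 600)
  ts <- preprocessRecording(x, rawRate = 600)
  expect_equal(nTrials(ts), 31L)
  expect_equal(dim(ts@data)[3L], 1500L)
  expect_equal(ts@samplingRate, 150)
  expect_identical(ts@reference, "average")
  cm <- colSums(aperm(ts@data, c(2L, 1L, 3L))) / 4
  expect_lt(max(abs(cm)), 1e-8)
  expect_error(preprocessRecording(x, rawRate = 500), "multiple of 150")
  expect_warning(short <- preprocessRecording(x[, 1:600], rawRate = 600),
                 "shorter")
  expect_equal(nTrials(short), 0L)
})

test_that("line noise at 50 Hz is removed by at least 40 dB", {
  fs <- 300
  t <- (0:(fs * 60 - 1)) / fs
  gains <- c(1, 2.5, 0.7)
  x <- outer(gains, sin(2 * pi * 50 * t)) +
    0.01 * matrix(rnorm(3 * length(t)), 3)
  ts <- preprocessRecording(x, rawRate = fs)
  # 50 Hz bin amplitude after the chain vs the raw input amplitude
  inputAmp <- mean(gains) / 2                # DFT amplitude of a unit sine
  outAmp <- mean(vapply(seq_len(nTrials(ts)), function(tr) {
    f <- stats::mvfft(t(ts@data[tr, , ]))
    mean(Mod(f[501L, ])) / 1500              # 50 Hz bin of 10 s at 150 Hz
  }, numeric(1L)))
  expect_lt(20 * log10(outAmp / inputAmp), -40)
})

test_that("band-pass shoulders attenuate 0.1 Hz and 74 Hz relative to 10 Hz", {
  set.seed(2)
  fs <- 600
  x <- matrix(rnorm(4 * fs * 120), 4)
  ts <- preprocessRecording(x, rawRate = fs)
  psd <- 0
  for (tr in seq_len(nTrials(ts)))
    psd <- psd + rowMeans(Mod(stats::mvfft(t(ts@data[tr, , ])))^2)
  freq <- (seq_along(psd) - 1) / 10          # 0.1 Hz resolution
  at <- function(f) psd[which.min(abs(freq - f))]
  expect_lt(at(0.1), 0.5 * at(10))
  expect_lt(at(74), 0.5 * at(10))
})

test_that("out-of-band tones do not alias into the decimated output", {
  fs <- 600
  t <- (0:(fs * 60 - 1)) / fs
  x <- matrix(rep(sin(2 * pi * 70.5 * t), 3), 3, byrow = TRUE) *
    matrix(c(1, -1, 0.5), 3, length(t))
  ts <- preprocessRecording(x, rawRate = fs)
  pow <- 0
  for (tr in seq_len(nTrials(ts)))
    pow <- pow + rowMeans(Mod(stats::mvfft(t(ts@data[tr, , ])))^2) /
      nTrials(ts)
  inputBinPow <- (mean(c(1, 1, 0.5)^2) / 4) * 1500^2  # tone power per bin scale
  expect_lt(max(pow), 0.01 * inputBinPow)
})

test_that("marked-trial removal takes neighbours and keeps order", {
  gen <- function(tr) matrix(tr, 2, 30)      # trial index encoded in the data
  ts <- makeTrialSet(10L, 2L, 3, 10, gen)
  kept <- function(x) unique(as.vector(x@data[, 1L, 1L]))
  expect_equal(kept(dropMarkedTrials(ts, 5L)), c(1, 2, 3, 4, 8, 9, 10))
  expect_equal(nTrials(dropMarkedTrials(ts, 5L)), 7L)
  expect_identical(dropMarkedTrials(ts, integer(0)), ts)
  expect_equal(kept(dropMarkedTrials(ts, 0L)), c(3, 4, 5, 6, 7, 8, 9, 10))
  expect_equal(kept(dropMarkedTrials(ts, c(0L, 9L))), c(3:8))
  expect_error(dropMarkedTrials(ts, 10L), "range")
})

test_that("trial selection is a seeded order-preserving subsample", {
  gen <- function(tr) matrix(tr, 2, 30)
  ts <- makeTrialSet(40L, 2L, 3, 10, gen)
  s1 <- selectTrials(ts, 30L, seed = 4L)
  s2 <- selectTrials(ts, 30L, seed = 4L)
  expect_equal(nTrials(s1), 30L)
  expect_identical(s1@data, s2@data)
  picked <- as.vector(s1@data[, 1L, 1L])
  expect_false(is.unsorted(picked))
  expect_equal(nTrials(selectTrials(ts, 40L, seed = 1L)), 40L)
  expect_error(selectTrials(ts, 41L, seed = 1L, subject = "S007"), "S007")
})
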