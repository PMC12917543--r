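test_that("subject simulation is deterministic and well-formed", {
  spec <- tinySpec(seed = 5L)
  r1 <- simulateSubject(spec, 1L)
  r2 <- simulateSubject(spec, 1L)
  expect_identical(r1@sensorData, r2@sensorData)
  expect_identical(r1@marks, r2@marks)
  expect_equal(dim(r1@sensorData), c(32L, 150L * 60L))
  expect_true(all(is.finite(r1@sensorData)))
  expect_error(simulateSubject(spec, 9L), "out of range")
})

test_that("control recordings are unaffected by the effect parameters", {
  base <- tinySpec(seed = 9L)
  effect <- tinySpec(seed = 9L,
                     bandEffects = c(delta = 1, theta = 2.5, alpha = 1,
                                     beta1 = 1, beta2 = 1, gamma = 1),
                     couplingEffect = c(delta = 0, theta = 0.8, alpha = 0,
                                        beta1 = 0, beta2 = 0, gamma = 0))
  ctrlA <- simulateSubject(base, 6L)     # control under either law
  ctrlB <- simulateSubject(effect, 6L)
  expect_identical(ctrlA@sensorData, ctrlB@sensorData)
  patA <- simulateSubject(base, 1L)
  patB <- simulateSubject(effect, 1L)
  expect_false(identical(patA@sensorData, patB@sensorData))
})

test_that("theta oscillators appear as a spectral peak near 6 Hz", {
  spec <- tinySpec(seed = 3L, markRate = 0, snr = 20)
  rec <- simulateSubject(spec, 5L)
  x <- rec@sensorData[1L, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = 150), spans = c(21, 21),
                         plot = FALSE, taper = 0.1)
  inTheta <- sp$spec[sp$freq >= 4 & sp$freq <= 8]
  shoulder <- sp$spec[sp$freq > 11 & sp$freq <= 14]
  expect_gt(max(inTheta), 1.5 * max(shoulder))
})

test_that("cohorts have the configured group sizes, covariates and truth", {
  spec <- cohortSpec(nPatients = 35L, nControls = 54L, nChannels = 19L,
                     verticesPerHemisphere = 42L, nRegions = 8L,
                     nNetworks = 4L, samplingRate = 150,
                     recordingLength = 10, seed = 2L)
  ch <- simulateCohort(spec)
  expect_length(ch$subjects, 89L)
  expect_equal(sum(ch$covariates$group == "patient"), 35L)
  expect_equal(sum(ch$covariates$group == "control"), 54L)
  expect_equal(sort(unique(ch$covariates$site)), 1:2)
  # sexes balanced within group up to one subject
  tab <- table(ch$covariates$sex, ch$covariates$group)
  expect_true(all(abs(tab[1L, ] - tab[2L, ]) <= 1L))
  expect_s4_class(ch$truth, "GroundTruth")
})

test_that("ground truth is nonzero exactly in the configured regions", {
  spec <- tinySpec(seed = 4L)
  tr <- groundTruth(spec)
  ss <- eegdens:::cohortContext(spec)$sourceSpace
  tv <- tr@powerMaps$theta
  expect_true(all(tv[ss@region %in% spec@activeRegions] > 0))
  expect_true(all(tv[!ss@region %in% spec@activeRegions] == 0))
  cv <- tr@connMaps$theta
  coupled <- unique(as.vector(spec@couplingPairs))
  expect_true(all(cv[!ss@region %in% coupled] == 0))
  expect_named(tr@powerMaps, "theta")
})

test_that("marked patients carry 3 Hz burst trials recorded as marks", {
  spec <- tinySpec(seed = 8L, markRate = 1)
  rec <- simulateSubject(spec, 2L)
  expect_gt(length(rec@marks), 0L)
  expect_true(all(rec@marks >= 0L & rec@marks < 6L))
  n10 <- 150L * 10L
  burstPow <- function(tr) {
    seg <- rec@sensorData[, tr * n10 + seq_len(n10)]
    f <- stats::mvfft(t(seg))
    mean(abs(f[31L, ])^2)                     # 3 Hz bin of a 10 s segment
  }
  clean <- setdiff(0:5, rec@marks)[1L]
  expect_gt(burstPow(rec@marks[1L]), 5 * burstPow(clean))
  # controls never carry marks
  expect_length(simulateSubject(spec, 7L)@marks, 0L)
})
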