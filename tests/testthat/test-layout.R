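test_that("layout construction covers the cap with protected 10-20 anchors", {
  lay <- fixLayout(256L, seed = 1L)
  expect_equal(nChannels(lay), 256L)
  expect_false(anyDuplicated(channelLabels(lay)) > 0)
  expect_length(protectedChannels(lay), 19L)
  expect_setequal(protectedChannels(lay),
                  c("Cz", "Fz", "Pz", "Fp1", "Fp2", "F3", "F4", "F7", "F8",
                    "C3", "C4", "T7", "T8", "P3", "P4", "P7", "P8", "O1", "O2"))
  # positions on the scalp shell, covering only the upper cap
  r <- sqrt(rowSums(channelPositions(lay)^2))
  expect_true(all(abs(r - 0.1) < 1e-9 * 0.1))
  expect_true(all(channelPositions(lay)[, 3L] > 0.1 * cos(2 * pi / 3) - 1e-9))
  # mirror pairing is an involution mapping left to right labels
  mir <- mirrorPairs(lay)
  expect_identical(unname(mir[mir[channelLabels(lay)]]), channelLabels(lay))
})

test_that("the minimal 19-channel layout is entirely protected and seeds reproduce", {
  lay <- buildLayout(19L, seed = 7L)
  expect_setequal(protectedChannels(lay), channelLabels(lay))
  expect_identical(buildLayout(37L, seed = 3L), buildLayout(37L, seed = 3L))
  expect_false(identical(channelPositions(buildLayout(37L, seed = 3L)),
                         channelPositions(buildLayout(37L, seed = 4L))))
  expect_error(buildLayout(18L), "19")
})

test_that("reduction hits the standard montage ladder and keeps all anchors", {
  lay <- fixLayout(256L, seed = 1L)
  for (target in c(192L, 128L, 64L, 48L, 32L, 25L, 19L)) {
    red <- reduceLayout(lay, target)
    expect_equal(nChannels(red), target)
    expect_true(all(protectedChannels(lay) %in% channelLabels(red)))
  }
  expect_identical(reduceLayout(lay, 256L), lay)
  expect_error(reduceLayout(lay, 18L), "protected")
})

test_that("reductions are nested and mirror-closed up to one parity channel", {
  lay <- fixLayout(64L, seed = 2L)
  via48 <- reduceLayout(reduceLayout(lay, 48L), 32L)
  direct <- reduceLayout(lay, 32L)
  expect_setequal(channelLabels(via48), channelLabels(direct))
  # odd intermediate target on the way down
  via25 <- reduceLayout(reduceLayout(lay, 25L), 19L)
  expect_setequal(channelLabels(via25), channelLabels(reduceLayout(lay, 19L)))
  for (target in c(48L, 33L, 25L)) {
    red <- reduceLayout(lay, target)
    mir <- mirrorPairs(red)
    lab <- channelLabels(red)
    unpaired <- sum(mir[lab] == lab &
                      abs(channelPositions(red)[, 1L]) > 1e-6 * 0.1)
    expect_lte(unpaired, 1L)
  }
})

test_that("greedy removal matches a brute-force replay of the rule on a toy layout", {
  # fixed 6-channel toy: 2 midline + 2 mirror pairs, one pair much denser
  dirs <- rbind(c(0, 0.6, 0.8), c(0, -0.6, 0.8),
                c(0.30, 0.1, 0.948), c(0.32, 0.1, 0.941),
                c(0.8, -0.2, 0.56), c(0.9, 0.1, 0.42))
  dirs <- rbind(dirs[1:2, ], dirs[3:6, ], dirs[3:6, ] * rep(c(-1, 1, 1), each = 4))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  lab <- c("M1", "M2", "R1", "R2", "R3", "R4", "L1", "L2", "L3", "L4")
  mir <- c(M1 = "M1", M2 = "M2", R1 = "L1", R2 = "L2", R3 = "L3", R4 = "L4",
           L1 = "R1", L2 = "R2", L3 = "R3", L4 = "R4")
  toy <- new("ElectrodeLayout", labels = lab, positions = dirs * 0.1,
             protected = character(0), mirror = mir, scalpRadius = 0.1)

  # independent replay: remove min-NN channel (ties by label), then partner
  alive <- lab
  removals <- character(0)
  pending <- NULL
  while (length(removals) < 6L) {
    if (!is.null(pending)) {
      drop <- pending; pending <- NULL
    } else {
      pos <- toy@positions[match(alive, lab), , drop = FALSE]
      d <- as.matrix(dist(pos)); diag(d) <- Inf
      nn <- apply(d, 1L, min)
      drop <- sort(alive[nn == min(nn)])[1L]
      partner <- unname(mir[drop])
      if (partner != drop && partner %in% setdiff(alive, drop)) pending <- partner
    }
    alive <- setdiff(alive, drop)
    removals <- c(removals, drop)
  }
  for (k in c(1L, 2L, 4L, 6L)) {
    red <- reduceLayout(toy, 10L - k)
    expect_setequal(channelLabels(red), setdiff(lab, removals[seq_len(k)]))
  }
})
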