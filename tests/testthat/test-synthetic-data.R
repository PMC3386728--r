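test_that("default config reproduces the study layout deterministically", {
  fs1 <- generateDataset(seed = 11)
  fs2 <- generateDataset(seed = 11)
  fs3 <- generateDataset(seed = 12)
  expect_equal(ncol(fs1), 480L)              # measurements
  expect_equal(nrow(fs1), 34L)               # 32 e-nose + 2 acoustic
  expect_equal(blockBoundary(fs1), 32L)
  expect_equal(dim(enoseBlock(fs1)), c(480L, 32L))
  expect_equal(dim(acousticBlock(fs1)), c(480L, 2L))
  expect_equal(as.vector(table(classLabels(fs1))), rep(80L, 6))
  expect_identical(featureMatrix(fs1), featureMatrix(fs2))
  expect_false(identical(featureMatrix(fs1), featureMatrix(fs3)))
  # sniff bookkeeping: first sniff already absent, 20 fruit x 4 sniffs/class
  si <- colData(fs1)$sniff_index
  expect_true(all(si %in% 2:5))
  expect_equal(length(unique(colData(fs1)$fruit_id)), 120L)
})

test_that("zero-noise limit reproduces the class means exactly", {
  specs <- separableSpecs(enoseSd = 0, acousticSd = 0, n = 8L)
  fs <- generateDataset(specs, seed = 5)
  x <- featureMatrix(fs)
  y <- classLabels(fs)
  for (k in 1:6) {
    rows <- x[y == k, , drop = FALSE]
    expect_equal(unname(rows[, 1:32]),
                 matrix(rep(specs[[k]]@enoseMean, each = 8), 8, 32))
    expect_equal(unname(rows[, 33:34]),
                 matrix(rep(specs[[k]]@acousticMean, each = 8), 8, 2))
  }
})

test_that("config invariants are enforced", {
  expect_error(generateDataset(separableSpecs()[1:5], seed = 1), "6 class")
  expect_error(defaultClassSpecs(enoseSd = 0), "positive")
  expect_error(defaultClassSpecs(acousticSd = -1), "positive")
  # duplicated (week, day) pair
  specs <- separableSpecs()
  specs[[2]] <- specs[[1]]
  expect_error(validateClassSpecs(specs), "exactly once")
  # week-7 e-nose means too close together
  specs <- separableSpecs(enoseSd = 1)
  specs[[2]]@enoseMean <- specs[[1]]@enoseMean + 0.1
  expect_error(validateClassSpecs(specs), "separate")
  # week-8 e-nose means too far apart
  specs <- separableSpecs(enoseSd = 1)
  specs[[5]]@enoseMean <- specs[[4]]@enoseMean + 2
  expect_error(validateClassSpecs(specs), "collapse")
  # acoustic means of day-differing classes too close
  specs <- separableSpecs(acousticSd = 5)
  expect_error(validateClassSpecs(specs), "6 sd apart")
})

test_that("per-class sample means converge to the configured means", {
  specs <- defaultClassSpecs(nSamples = 1000L)
  fs <- generateDataset(specs, seed = 42)
  x <- featureMatrix(fs)
  y <- classLabels(fs)
  for (k in 1:6) {
    mu <- colMeans(x[y == k, ])
    target <- c(specs[[k]]@enoseMean, specs[[k]]@acousticMean)
    sds <- c(rep(specs[[k]]@enoseSd, 32), rep(specs[[k]]@acousticSd, 2))
    expect_true(all(abs(mu - target) <= 3 * sds / sqrt(1000)))
  }
})

test_that("fused means separate six classes but e-nose means only four groups", {
  specs <- defaultClassSpecs()
  em <- do.call(rbind, lapply(specs, function(s) s@enoseMean))
  am <- do.call(rbind, lapply(specs, function(s) s@acousticMean))
  # exact oracle on the noiseless means: distinct e-nose patterns
  expect_equal(nrow(unique(round(em, 10))), 4L)
  # fused whitened means: all 15 pairs at least 6 sd apart
  fused <- cbind(em / specs[[1]]@enoseSd, am / specs[[1]]@acousticSd)
  d <- as.matrix(dist(fused))
  expect_true(all(d[upper.tri(d)] >= 6))
  # acoustic firmness pattern: Green firmer on day 2, reversed later
  expect_gt(am[1, 1], am[4, 1])
  expect_lt(am[2, 1], am[5, 1])
  expect_lt(am[3, 1], am[6, 1])
})

test_that("sniff traces follow the first-order rise and recover the smellprint", {
  specs <- defaultClassSpecs()
  tr <- generateSniffTrace(2, seed = 1, noiseSd = 0)
  s0 <- extractBaseline(tr)
  smax <- extractSmax(tr)
  # clean trace: baseline exact, fractional response within 1% of the mean
  expect_equal(unname(s0), 800 + 20 * (0:31))
  sfrac <- fractionalResponse(s0, smax)
  A <- specs[[2]]@enoseMean
  expect_true(all(abs(sfrac - A) <= 0.01 * abs(A)))
  # the rise starts at zero: at draw onset resistance equals baseline
  iOnset <- which(tr@time == 10)
  expect_equal(unname(tr@resistance[iOnset, ]), unname(s0))
  # zero amplitude on every channel gives an all-zero smellprint
  flat <- separableSpecs()
  flat[[1]]@enoseMean <- rep(0, 32)
  tr0 <- generateSniffTrace(1, seed = 1, specs = flat, noiseSd = 0)
  expect_equal(unname(traceFractionalResponse(tr0)$values), rep(0, 32))
  # invalid class and determinism under noise
  expect_error(generateSniffTrace(9, seed = 1), "invalid classId")
  n1 <- generateSniffTrace(1, seed = 7, noiseSd = 0.01)
  n2 <- generateSniffTrace(1, seed = 7, noiseSd = 0.01)
  expect_identical(n1@resistance, n2@resistance)
})

test_that("toy competitive-layer fixture matches the printed values", {
  fx <- toyClnnFixture()
  expect_equal(unname(fx$p["p2", ]), c(0.196, 0.981))
  expect_equal(unname(fx$w["w3", ]), c(-1, 0))
  expect_equal(fx$alpha, 0.5)
  norms <- sqrt(rowSums(fx$w^2))
  expect_true(all(abs(norms - 1) <= 0.001))
})
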