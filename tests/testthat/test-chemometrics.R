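test_that("the 80% cumulative-variance rule picks the documented component counts", {
  expect_equal(componentsForVariance(c(0.60, 0.25, 0.10, 0.05)), 2L)
  expect_equal(componentsForVariance(rep(0.25, 4)), 4L)
  expect_equal(componentsForVariance(c(0.8, 0.2)), 1L)
  expect_error(componentsForVariance(c(0.5, 0.2)), "summing to 1")
})

test_that("PCA loadings are orthonormal and reconstruction is exact", {
  set.seed(31)
  x <- matrix(rnorm(200), 20, 10) %*% diag(seq(3, 0.5, length.out = 10))
  m <- pcaFit(x)
  G <- crossprod(m@loadings)
  expect_equal(G, diag(10), tolerance = 1e-8)
  expect_equal(sum(varianceRatios(m)), 1, tolerance = 1e-8)
  expect_true(all(diff(varianceRatios(m)) <= 1e-12))
  centred <- sweep(x, 2, m@center)
  expect_equal(centred %*% m@loadings %*% t(m@loadings), centred,
               tolerance = 1e-8, ignore_attr = TRUE)
  # rank-1 data: the first component carries everything
  line <- cbind(1:20, 2 * (1:20))
  ml <- pcaFit(line)
  expect_equal(varianceRatios(ml)[1], 1, tolerance = 1e-10)
  expect_equal(nRetained(ml), 1L)
  expect_error(pcaFit(line[1, , drop = FALSE]), "at least 2 rows")
})

test_that("LDA matches the nearest-class-mean oracle and an independent fit", {
  set.seed(32)
  cl <- gaussianClusters(K = 3L, nPer = 15L, dims = 4L, sep = 8, sd = 1)
  m <- ldaFit(cl$x, cl$y)
  expect_equal(ncol(discriminants(m)), 2L)  # min(g - 1, p)
  pred <- predict(m, cl$x)
  # oracle 1: brute-force nearest class mean in the full discriminant space
  sc <- predict(m, cl$x, type = "scores")
  centroids <- rowsum(sc, cl$y) / as.vector(table(cl$y))
  nearest <- apply(sc, 1, function(r)
    which.min(colSums((t(centroids) - r)^2)))
  expect_equal(as.integer(pred), unname(nearest))
  # oracle 2: an established LDA implementation agrees on every assignment
  ml <- MASS::lda(cl$x, grouping = cl$y,
                  prior = rep(1 / 3, 3))
  expect_equal(as.character(pred),
               as.character(predict(ml, cl$x)$class))
})

test_that("LDA degenerates and invariances behave as theory demands", {
  # six well-separated classes give five discriminants
  d <- preparedDefault(seed = 33)
  m6 <- ldaFit(d$x, d$y)
  expect_equal(ncol(discriminants(m6)), 5L)
  expect_true(all(diff(m6@eigenvalues) <= 1e-8))
  # two classes with identical means: no between-class variance
  set.seed(34)
  x0 <- matrix(rnorm(400), 200, 2)
  y0 <- factor(rep(1:2, each = 100))
  m0 <- ldaFit(x0, y0)
  expect_lt(m0@eigenvalues[1], 0.2)
  # assignments invariant under a common invertible affine map
  set.seed(35)
  cl <- gaussianClusters(K = 3L, nPer = 20L, dims = 3L, sep = 6, sd = 1)
  A <- matrix(rnorm(9), 3) + 3 * diag(3)
  shifted <- sweep(cl$x %*% A, 2, c(5, -2, 7), `+`)
  expect_equal(as.integer(predict(ldaFit(cl$x, cl$y), cl$x)),
               as.integer(predict(ldaFit(shifted, cl$y), shifted)))
  # singular within-class scatter triggers the ridge warning
  xs <- cbind(cl$x, cl$x[, 1])
  expect_warning(ldaFit(xs, cl$y), "ridge")
})

test_that("leave-one-out cross-validation separates, nulls and counts errors correctly", {
  # separable limit: both resubstitution and LOO are perfect
  cl <- gaussianClusters(K = 3L, nPer = 10L, dims = 3L, sep = 30, sd = 0.05)
  rep1 <- looCrossValidate(cl$x, cl$y)
  expect_equal(accuracy(rep1, "original"), 100)
  expect_equal(accuracy(rep1, "cv"), 100)
  expect_equal(unname(rowSums(confusionCounts(rep1, "cv"))), rep(10, 3))
  # one mislabelled point in a separable set costs exactly one LOO error
  yFlip <- cl$y
  yFlip[4] <- "2"
  repFlip <- looCrossValidate(cl$x, yFlip)
  cm <- confusionCounts(repFlip, "cv")
  expect_equal(sum(cm) - sum(diag(cm)), 1L)
  expect_equal(cm["2", "1"], 1L)  # the flipped point returns to its cluster
  # permutation null: shuffled labels on 6 balanced classes sit near chance
  d <- preparedDefault(seed = 36)
  set.seed(36)
  yShuf <- sample(d$y)
  repNull <- looCrossValidate(d$x, yShuf)
  expect_lt(abs(accuracy(repNull, "cv") - 100 / 6), 5)
  # LOO never beats resubstitution on this generator
  expect_lte(accuracy(repNull, "cv"), accuracy(repNull, "original"))
})

test_that("Wilks' lambda screening equals the one-way ANOVA oracle", {
  set.seed(37)
  n <- 40L
  y <- factor(rep(1:4, each = 10))
  x <- cbind(rnorm(n), rnorm(n) + as.integer(y), rnorm(n, sd = 2))
  colnames(x) <- c("noise", "signal", "noise2")
  w <- wilksScreen(x, y, alpha = 0.05)
  for (j in 1:3) {
    # direct summation oracle
    ssw <- sum(tapply(x[, j], y, function(v) sum((v - mean(v))^2)))
    sst <- sum((x[, j] - mean(x[, j]))^2)
    lam <- ssw / sst
    expect_equal(w$lambda[j], lam, tolerance = 1e-10)
    expect_equal(w$F[j], (1 - lam) / lam * (n - 4) / 3, tolerance = 1e-10)
    # established ANOVA implementation agrees
    fit <- summary(stats::aov(x[, j] ~ y))[[1]]
    expect_equal(w$F[j], fit[["F value"]][1], tolerance = 1e-8)
    expect_equal(w$p.value[j], fit[["Pr(>F)"]][1], tolerance = 1e-8)
  }
  expect_true(w$keep[2])
  # a column whose class means coincide exactly: Lambda = 1, F = 0, dropped
  xc <- cbind(x, flat = rep(c(1, 2), 20))
  wc <- wilksScreen(xc, factor(rep(1:2, each = 20)))
  expect_equal(wc$lambda[4], 1)
  expect_equal(wc$F[4], 0)
  expect_false(wc$keep[4])
  # zero within-class variance with distinct means: F explodes, kept
  xz <- cbind(x, pure = as.integer(y))
  wz <- wilksScreen(xz, y)
  expect_gt(wz$F[4], 1e10)
  expect_true(wz$keep[4])
  # zero total variance is an error
  expect_error(wilksScreen(cbind(x, dead = 5), y), "zero total variance")
})

test_that("screening feeds cross-validation through the keep flags", {
  set.seed(38)
  cl <- gaussianClusters(K = 3L, nPer = 20L, dims = 2L, sep = 10, sd = 0.5)
  x <- cbind(cl$x, matrix(rnorm(120), 60, 2))  # two pure-noise columns
  colnames(x) <- c("s1", "s2", "n1", "n2")
  w <- wilksScreen(x, cl$y)
  expect_true(all(w$keep[1:2]))
  expect_false(any(w$keep[3:4]))
  rep1 <- looCrossValidate(x, cl$y, screen = w)
  expect_equal(accuracy(rep1, "cv"), 100)
})
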