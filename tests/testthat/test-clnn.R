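test_that("net input is negative distance plus bias, maximal at the weight", {
  fx <- toyClnnFixture()
  n <- netInput(fx$w[1, ], fx$w, 0)
  expect_equal(n[1], 0)
  expect_equal(which.max(n), 1L)
  # with zero biases every net input is non-positive
  expect_true(all(netInput(c(3, -2), fx$w, 0) < 0))
  # bias additivity: shifting one bias shifts that net input exactly
  b <- c(0, 0.25, 0)
  expect_equal(netInput(fx$p[1, ], fx$w, b) - netInput(fx$p[1, ], fx$w, 0), b)
  expect_error(netInput(1:3, fx$w), "dimension")
})

test_that("competition returns a one-hot winner with lowest-index tie-break", {
  r <- compete(c(-2, -0.5, -1))
  expect_equal(r$winner, 2L)
  expect_equal(r$a, c(0, 1, 0))
  expect_equal(sum(r$a), 1)
  expect_equal(compete(c(-1, -0.3, -0.3))$winner, 2L)
  expect_error(compete(numeric()), "empty")
  # zero-distance case: an input equal to a weight wins outright
  fx <- toyClnnFixture()
  expect_equal(compete(netInput(fx$w[3, ], fx$w, 0))$winner, 3L)
})

test_that("the printed worked example reproduces exactly", {
  fx <- toyClnnFixture()
  res <- compete(netInput(fx$p["p2", ], fx$w, 0))
  expect_equal(res$winner, 2L)
  expect_equal(res$a[2], 1)
  w2new <- kohonenUpdate(fx$w["w2", ], fx$p["p2", ], fx$alpha)
  expect_lt(max(abs(w2new - c(0.451, 0.844))), 0.001)
  expect_equal(unname(w2new), c(0.4515, 0.844))
})

test_that("the Kohonen rule is an exact contraction toward the input", {
  set.seed(41)
  for (i in 1:20) {
    w <- rnorm(3); p <- rnorm(3); a <- runif(1)
    w2 <- kohonenUpdate(w, p, a)
    expect_equal(sqrt(sum((w2 - p)^2)), (1 - a) * sqrt(sum((w - p)^2)),
                 tolerance = 1e-12)
  }
  w <- c(1, 2)
  expect_equal(kohonenUpdate(w, c(5, 5), 0), w)
  expect_equal(kohonenUpdate(w, c(5, 5), 1), c(5, 5))
  expect_error(kohonenUpdate(w, c(5, 5), 1.2), "alpha")
})

test_that("conscience biases revive persistent losers and settle at equal wins", {
  S <- 4L
  c0 <- rep(1 / S, S)
  # lambda = 0 changes nothing
  u0 <- biasUpdate(c0, winner = 2L, lambda = 0)
  expect_equal(u0$c, c0)
  # equal rotation of winners converges to the uniform fixed point
  cc <- c(0.7, 0.1, 0.1, 0.1)
  for (i in 1:5000) cc <- biasUpdate(cc, (i %% S) + 1L, 0.01)$c
  expect_equal(cc, rep(1 / S, S), tolerance = 0.02)
  expect_equal(sum(cc), 1, tolerance = 1e-8)
  # a neuron that never wins gains bias strictly monotonically
  cc <- rep(1 / S, S)
  bTrace <- numeric(50)
  for (i in 1:50) {
    u <- biasUpdate(cc, 1L, 0.01)
    cc <- u$c
    bTrace[i] <- u$b[3]
  }
  expect_true(all(diff(bTrace) > 0))
  # the winner's bias falls toward 0 as its win frequency approaches 1
  cc <- rep(1 / S, S)
  for (i in 1:5000) cc <- biasUpdate(cc, 1L, 0.01)$c
  expect_equal(exp(1 - log(cc[1])) - exp(1), 0, tolerance = 0.02)
})

test_that("zero-bias competition is a brute-force nearest-neighbour rule", {
  set.seed(42)
  for (i in 1:50) {
    W <- matrix(rnorm(12), 4, 3)
    p <- rnorm(3)
    winner <- compete(netInput(p, W, 0))$winner
    expect_equal(winner, which.min(rowSums(sweep(W, 2, p)^2)))
  }
})

test_that("training updates only the winning weight and honours epochs", {
  W0 <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  x1 <- matrix(1, 2, 2)  # two identical presentations of (1, 1)
  m0 <- clnnTrain(x1, neurons = 2L, epochs = 0L, repeats = 1L, seed = 1,
                  initWeights = W0)
  expect_equal(clnnWeights(m0), W0)
  m1 <- clnnTrain(x1, neurons = 2L, alpha = 0.5, epochs = 1L, repeats = 1L,
                  seed = 1, initWeights = W0)
  changed <- rowSums(clnnWeights(m1) != W0) > 0
  expect_equal(sum(changed), 1L)  # the loser never moves
  # winner halves its distance on each of the two presentations
  expect_equal(clnnWeights(m1)[1, ], c(0.75, 0.75))
  expect_error(clnnTrain(x1, neurons = 5L), "more neurons than")
})

test_that("a single neuron converges to the centroid of one cluster", {
  set.seed(43)
  x <- matrix(rnorm(200, sd = 0.3), 100, 2) + 3
  m <- clnnTrain(x, neurons = 1L, alpha = 0.1, epochs = 50L, repeats = 1L,
                 seed = 7)
  expect_lt(sqrt(sum((clnnWeights(m) - colMeans(x))^2)), 0.15)
})

test_that("the toy example clusters into its three visual groups", {
  fx <- toyClnnFixture()
  m <- clnnTrain(fx$p, neurons = 3L, alpha = fx$alpha, biasLR = 0.001,
                 epochs = 50L, repeats = 1L, seed = 2, initWeights = fx$w)
  centroids <- rbind(colMeans(fx$p[1:2, ]),    # upper pair
                     colMeans(fx$p[3:5, ]),    # right trio
                     colMeans(fx$p[6:7, ]))    # lower-left pair
  W <- clnnWeights(m)
  d <- sqrt(outer(rowSums(W^2), rowSums(centroids^2), `+`) -
              2 * W %*% t(centroids))
  nearest <- apply(d, 1, which.min)
  expect_equal(sort(nearest), 1:3)             # one neuron per cluster
  expect_true(all(apply(d, 1, min) < 0.15))
})

test_that("trained weights recover planted centroids across seeds", {
  devs <- c()
  for (s in 1:10) {
    set.seed(100 + s)
    cl <- gaussianClusters(K = 4L, nPer = 25L, dims = 2L, sep = 10, sd = 0.3)
    m <- clnnTrain(cl$x, neurons = 4L, alpha = 0.1, biasLR = 0.001,
                   epochs = 40L, repeats = 3L, seed = 200 + s,
                   init = "random")
    W <- clnnWeights(m)
    d <- sqrt(outer(rowSums(W^2), rowSums(cl$centres^2), `+`) -
                2 * W %*% t(cl$centres))
    nearest <- apply(d, 1, which.min)
    expect_equal(sort(nearest), 1:4)  # a neuron per planted cluster
    devs <- c(devs, apply(d, 1, min))
  }
  se <- 0.3 / sqrt(25)
  expect_lt(median(devs), 3 * se)
})

test_that("conscience learning keeps every neuron alive when clusters abound", {
  for (s in 1:5) {
    set.seed(300 + s)
    cl <- gaussianClusters(K = 4L, nPer = 20L, dims = 2L, sep = 10, sd = 0.3)
    m <- clnnTrain(cl$x, neurons = 3L, alpha = 0.1, biasLR = 0.001,
                   epochs = 40L, repeats = 1L, seed = 400 + s)
    am <- assignAndMap(m, cl$x, cl$y)
    expect_equal(sort(unique(am$assignments)), 1:3)
  }
})

test_that("neuron-class mapping counts detected classes", {
  set.seed(44)
  cl <- gaussianClusters(K = 6L, nPer = 20L, dims = 3L, sep = 12, sd = 0.3)
  m <- clnnTrain(cl$x, neurons = 6L, alpha = 0.1, epochs = 40L, repeats = 3L,
                 seed = 5, init = "random")
  am <- assignAndMap(m, cl$x, cl$y)
  expect_equal(am$nClassesDetected, 6L)
  expect_true(all(!is.na(am$classMap)))
  # everything labelled class 1 detects a single class
  am1 <- assignAndMap(m, cl$x, factor(rep(1, nrow(cl$x))))
  expect_equal(am1$nClassesDetected, 1L)
  # mapped model classifies held-out points from the same clusters
  pred <- predict(am$model, cl$centres)
  expect_equal(as.integer(sort(pred)), 1:6)
})

test_that("split evaluation respects the 25/75 protocol and its limits", {
  d <- preparedDefault(seed = 45)
  ev <- evaluateSplit(d$x, d$y, trainFrac = 0.25, seed = 46)
  expect_equal(ev$trainN, 120L)
  expect_equal(ev$testN, 360L)
  # separable limit: perfect held-out accuracy
  cl <- gaussianClusters(K = 3L, nPer = 40L, dims = 3L, sep = 30, sd = 0.05)
  ev0 <- evaluateSplit(cl$x, cl$y, seed = 47, neurons = 3L, scoreDims = 2L,
                       epochs = 60L)
  expect_equal(ev0$accuracy, 100)
  expect_equal(ev0$nClustersDetected, 3L)
  # permutation null: shuffled labels fall to chance
  set.seed(48)
  evNull <- evaluateSplit(d$x, sample(d$y), seed = 49, epochs = 50L)
  expect_lt(abs(evNull$accuracy - 100 / 6), 5)
})
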