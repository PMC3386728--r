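# Small in-code fixtures shared across the suite.

# Six-class spec list with fully separated means everywhere (used for
# zero-noise / separable-limit checks; mature e-nose means identical when
# sd = 0 so the collapse invariant holds in the degenerate limit).
separableSpecs <- function(enoseSd = 0, acousticSd = 0, n = 8L) {
  base <- rep(1, 32)
  u <- diag(32)
  em <- rbind(base,
              base + 10 * u[1, ],
              base + 10 * u[2, ],
              base + 10 * u[3, ],
              base + 10 * u[3, ],
              base + 10 * u[3, ])
  am <- rbind(c(30, 60), c(20, 50), c(10, 40),
              c(29, 59), c(19, 49), c(9, 39))
  weeks <- c(7L, 7L, 7L, 8L, 8L, 8L)
  days <- c(2L, 4L, 7L, 2L, 4L, 7L)
  lapply(1:6, function(k)
    classSpec(k, weeks[k], days[k], em[k, ], am[k, ],
              enoseSd = enoseSd, acousticSd = acousticSd, nSamples = n))
}

# K isotropic Gaussian clusters, centres on a circle of radius `sep` in the
# first two dimensions (pairwise centre distance >= sep for K <= 6).
gaussianClusters <- function(K = 3L, nPer = 20L, dims = 2L, sep = 10,
                             sd = 0.3) {
  centres <- matrix(0, K, dims)
  centres[, 1] <- sep * cos(2 * pi * seq_len(K) / K)
  centres[, 2] <- sep * sin(2 * pi * seq_len(K) / K)
  x <- do.call(rbind, lapply(seq_len(K), function(k)
    sweep(matrix(rnorm(nPer * dims, sd = sd), nPer, dims), 2,
          centres[k, ], `+`)))
  list(x = x, y = factor(rep(seq_len(K), each = nPer)), centres = centres)
}

# The pipeline's standard preprocessing path from a generated FeatureSet.
preparedDefault <- function(seed, modality = "fused") {
  fs <- generateDataset(seed = seed, includeFirstSniff = TRUE)
  fs <- suppressWarnings(discardFirstSniff(fs))
  list(x = prepareFeatures(fs, modality), y = classLabels(fs))
}
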