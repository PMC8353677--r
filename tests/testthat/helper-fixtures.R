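# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A StimulusMatrix carrying arbitrary series on arbitrary time stamps.
mkStim <- function(values, times, duration = max(times) + 1,
                   standardized = TRUE) {
  values <- rbind(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  new("StimulusMatrix", values = values, wordTimes = times,
      duration = duration, standardized = standardized)
}

mkResampled <- function(values, tr = 1) {
  values <- rbind(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  new("ResampledDesign", values = values, tr = tr)
}

# A tiny embedding table from an explicit named list of vectors.
mkEmb <- function(...) {
  vs <- list(...)
  EmbeddingTable(do.call(rbind, vs))
}

# Random embedding table of n unit vectors in `dim` dimensions.
randEmb <- function(n, dim, seed = 1, prefix = "w") {
  set.seed(seed)
  v <- matrix(rnorm(n * dim), n, dim)
  v <- v / sqrt(rowSums(v^2))
  rownames(v) <- sprintf("%s%04d", prefix, seq_len(n))
  EmbeddingTable(v)
}

# Adjusted Rand index between two labelings (independent oracle: mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Planted 4-D blobs: k tight Gaussian clusters far apart.
plantedBlobs <- function(k = 4, perCluster = 25, dims = 4, sep = 10,
                         sd = 0.2, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dims), k, dims) * sep
  labels <- rep(seq_len(k), each = perCluster)
  x <- centers[labels, ] + matrix(rnorm(k * perCluster * dims, sd = sd),
                                  k * perCluster, dims)
  rownames(x) <- sprintf("p%03d", seq_len(nrow(x)))
  list(x = x, labels = labels)
}

# Brute-force single-linkage agglomeration by repeated pairwise-minimum
# merging; oracle for nearestNeighborClusters on small inputs.
bruteSingleLinkage <- function(points, k) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  groups <- as.list(seq_len(n))
  while (length(groups) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i < j) {
          m <- min(d[groups[[i]], groups[[j]]])
          if (m < best[1]) best <- c(m, i, j)
        }
      }
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

# Small synthetic configuration that keeps every stage fast.
smallConfig <- function(seed = 1, ...) {
  args <- list(nVocabWords = 80, embeddingDim = 16, nPlantedClusters = 3,
               nFeatureWords = 30, runDuration = 80, wordRate = 2,
               tr = 1, delays = c(2, 4), nVoxels = 60, noiseSd = 1,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(syntheticConfig, args)
}
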