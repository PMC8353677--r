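test_that("delay averaging collapses feature-major copies to their mean", {
  # one voxel, one feature with copies (1,2,3,4) -> 2.5
  w <- matrix(c(1, 2, 3, 4), 1)
  expect_equal(as.numeric(averageDelays(w, 4)), 2.5)
  # equal copies return the copy
  w2 <- matrix(rep(c(7, -2), each = 3), 1)
  expect_equal(as.numeric(averageDelays(w2, 3)), c(7, -2))
  # shape contract and indivisibility error
  w3 <- matrix(rnorm(5 * 12), 5)
  expect_equal(dim(averageDelays(w3, 4)), c(5L, 3L))
  expect_error(averageDelays(w3, 5), "not divisible")
  # averaging an EncodingResult reuses its stored delay count
  st <- generateSyntheticStudy(smallConfig(seed = 2))
  enc <- fitEncodingModel(st$design, st$bold, alphas = 10, probeVoxels = 10)
  expect_equal(ncol(averageDelays(enc)), 30L)
})

test_that("delay averaging agrees with a per-feature loop oracle", {
  set.seed(31)
  nv <- 4; nf <- 6; nd <- 3
  w <- matrix(rnorm(nv * nf * nd), nv)
  got <- averageDelays(w, nd)
  for (j in seq_len(nv)) {
    for (i in seq_len(nf)) {
      expect_equal(got[j, i], mean(w[j, (i - 1) * nd + seq_len(nd)]))
    }
  }
})

test_that("top-voxel selection is a deterministic sort with stable ties", {
  expect_equal(selectTopVoxels(c(0.1, 0.9, 0.5), 2), c(2L, 3L))
  expect_equal(selectTopVoxels(c(0.1, 0.9, 0.5), 3), 1:3)
  # ties: lower index wins
  expect_equal(selectTopVoxels(c(0.5, 0.9, 0.5), 2), c(1L, 2L))
  set.seed(32)
  r <- rnorm(200)
  n <- 37
  oracle <- sort(order(r, decreasing = TRUE)[seq_len(n)])
  expect_equal(selectTopVoxels(r, n), oracle)
  expect_error(selectTopVoxels(r, 0), "positive")
  expect_error(selectTopVoxels(r, 300), "exceeds")
})

test_that("PCA is centered, orthonormal and matches an eigendecomposition", {
  set.seed(33)
  W <- matrix(rnorm(24), 6, 4)
  sp <- pcaFit(W, 2)
  L <- pcaLoadings(sp)
  expect_equal(crossprod(L), diag(2), tolerance = 1e-8, ignore_attr = TRUE)
  # scores are the centered data projected on the loadings
  expect_equal(pcaScores(sp), scale(W, scale = FALSE) %*% L,
               tolerance = 1e-8, ignore_attr = TRUE)
  # eigensolver oracle (covariance with n-1 denominator), up to sign
  ev <- eigen(cov(W))
  for (k in 1:2) {
    expect_equal(abs(sum(L[, k] * ev$vectors[, k])), 1, tolerance = 1e-8)
  }
  expect_equal(explainedVariance(sp),
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-8)
  # sign convention: the largest-|loading| entry is positive
  for (k in 1:2) expect_gt(L[which.max(abs(L[, k])), k], 0)
})

test_that("rank-1 data explain all variance in one component; rank errors are informative", {
  u <- rnorm(10); v <- rnorm(5)
  W <- outer(u, v)
  sp <- pcaFit(W, 1)
  expect_equal(explainedVariance(sp)[1], 1, tolerance = 1e-8)
  expect_error(pcaFit(W, 3), "rank 1")
  expect_error(pcaFit(matrix(rnorm(12), 3, 4), 4), "observations")
})

test_that("k-means recovers planted blobs and is deterministic", {
  pb <- plantedBlobs(k = 4, perCluster = 25, seed = 41)
  cm <- kmeansFeatures(pb$x, k = 4, seed = 7)
  expect_equal(ari(clusterLabels(cm), pb$labels), 1)
  # independent cross-check: stats::kmeans finds the same partition here
  km <- kmeans(pb$x, centers = 4, nstart = 10)
  expect_equal(ari(clusterLabels(cm), km$cluster), 1)
  # determinism
  cm2 <- kmeansFeatures(pb$x, k = 4, seed = 7)
  expect_identical(clusterLabels(cm), clusterLabels(cm2))
  expect_identical(clusterCenters(cm), clusterCenters(cm2))
  # k = 1: a single centroid
  one <- kmeansFeatures(pb$x, k = 1, seed = 1)
  expect_true(all(clusterLabels(one) == 1L))
  expect_equal(clusterCenters(one)[1, ], colMeans(pb$x),
               ignore_attr = TRUE)
  expect_error(kmeansFeatures(pb$x[1:3, ], k = 5), "exceeds")
})

test_that("k-means inertia equals the within-cluster sum of squares", {
  pb <- plantedBlobs(k = 3, perCluster = 15, seed = 42)
  cm <- kmeansFeatures(pb$x, k = 3, seed = 3)
  lab <- clusterLabels(cm)
  wss <- sum(sapply(1:3, function(cl) {
    xs <- pb$x[lab == cl, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }))
  expect_equal(clusterInertia(cm), wss, tolerance = 1e-8)
})

test_that("cluster localization keeps the top-scoring voxel fraction", {
  set.seed(43)
  nv <- 40; nf <- 6
  w <- matrix(rnorm(nv * nf), nv, nf,
              dimnames = list(NULL, paste0("f", 1:nf)))
  coords <- cbind(seq_len(nv), 1L, 1L)
  labels <- structure(rep(1L, nf), names = colnames(w))
  model <- new("ClusterModel", labels = labels,
               centers = matrix(0, 1, 2), k = 1L, seed = 1L, inertia = 0)
  loc <- localizeClusters(w, model, coords, topFraction = 0.25)
  tab <- localizationTable(loc)
  score <- rowMeans(w)
  oracle <- sort(order(score, decreasing = TRUE)[1:10])
  expect_equal(tab$voxel, oracle)
  expect_equal(tab$score, score[oracle])
})

test_that("block-structured weights localize each cluster to its voxel block", {
  nf <- 9; nv <- 30
  labels <- structure(rep(1:3, each = 3), names = paste0("f", 1:nf))
  w <- matrix(0, nv, nf, dimnames = list(NULL, names(labels)))
  block <- rep(1:3, each = 10)
  for (b in 1:3) w[block == b, labels == b] <- 1
  model <- new("ClusterModel", labels = labels,
               centers = matrix(0, 3, 2), k = 3L, seed = 1L, inertia = 0)
  loc <- localizeClusters(w, model, cbind(1:nv, 1L, 1L),
                          topFraction = 1 / 3)
  tab <- localizationTable(loc)
  for (b in 1:3) {
    expect_setequal(tab$voxel[tab$cluster == b], which(block == b))
  }
})

test_that("degenerate localizations warn but stay deterministic", {
  nf <- 4
  labels <- structure(c(1L, 1L, 1L, 1L), names = paste0("f", 1:nf))
  w <- matrix(0, 10, nf, dimnames = list(NULL, names(labels)))
  model <- new("ClusterModel", labels = labels,
               centers = matrix(0, 2, 2), k = 2L, seed = 1L, inertia = 0)
  expect_warning(loc <- localizeClusters(w, model, cbind(1:10, 1L, 1L),
                                         topFraction = 0.2),
                 "empty")
  tab <- localizationTable(loc)
  expect_true(all(tab$cluster == 1))
  expect_equal(tab$voxel, 1:2)  # zero scores tie-break to lowest indices
  expect_true(all(tab$score == 0))
})
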