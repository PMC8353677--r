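test_that("seed lists are split, deduplicated and validated", {
  emb <- randEmb(6, 4)
  w <- rownames(embeddingVectors(emb))
  expect_equal(suppressMessages(threatSeedList(c(w[1], w[1], w[2]), emb)),
               w[1:2])
  expect_message(threatSeedList(c(w[1], w[1]), emb), "duplicate")
  # whitespace-separated collocations become individual seeds
  expect_equal(threatSeedList(paste(w[3], w[4]), emb), w[3:4])
  expect_error(threatSeedList("absent", emb), "out-of-vocabulary")
})

test_that("a clear outlier is always selected as peripheral", {
  x <- rbind(matrix(rnorm(40 * 2, sd = 0.01), 40, 2),
             c(50, 50))
  sel <- selectPeripheralPoints(x, fraction = 0.8, repeats = 20, seed = 4)
  expect_true(41 %in% sel)
  # determinism under a fixed seed
  sel2 <- selectPeripheralPoints(x, fraction = 0.8, repeats = 20, seed = 4)
  expect_identical(sel, sel2)
  expect_error(selectPeripheralPoints(x[1:4, ]), "at least 5")
  expect_error(selectPeripheralPoints(x, fraction = 1.2), "fraction")
})

test_that("with one near-complete draw selection reduces to centroid-distance ranking", {
  set.seed(45)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3)
  frac <- (n - 1) / n  # draw all but one point, once
  sel <- selectPeripheralPoints(x, fraction = frac, repeats = 1, seed = 9)
  d <- sqrt(rowSums(sweep(x, 2, colMeans(x))^2))
  # everything selected sits at the top of the plain centroid-distance
  # ranking (one point is unseen by the draw, hence the slack of one)
  expect_true(all(sel %in% order(d, decreasing = TRUE)[1:(length(sel) + 1)]))
})

test_that("single linkage recovers separated segments and matches brute force", {
  seg1 <- cbind(seq(0, 1, length.out = 6), 0)
  seg2 <- cbind(seq(10, 11, length.out = 6), 0)
  lab <- nearestNeighborClusters(rbind(seg1, seg2), k = 2)
  expect_equal(length(unique(lab[1:6])), 1L)
  expect_equal(length(unique(lab[7:12])), 1L)
  expect_true(lab[1] != lab[7])
  # k = n: singletons
  labN <- nearestNeighborClusters(seg1, k = 6)
  expect_equal(sort(unique(labN)), 1:6)
  expect_error(nearestNeighborClusters(seg1, k = 10), "exceeds")
  # chaining: exhaustive pairwise-minimum merge oracle on 10 points
  set.seed(46)
  pts <- cbind(c(seq(0, 2, length.out = 7), 8, 8.3, 8.6), rnorm(10, sd = 0.01))
  for (k in c(2, 3, 5)) {
    expect_equal(ari(nearestNeighborClusters(pts, k),
                     bruteSingleLinkage(pts, k)), 1)
  }
})

test_that("median threat distance follows the mean-then-median recipe", {
  emb <- mkEmb(a = c(1, 0), b = c(0, 1), c = c(1, 1), d = c(1, 0.2))
  seeds <- c("a", "b")
  # single-word cluster: median = mean distance of that word to the seeds
  d_c <- mean(c(1 - cosineSimilarity(c(1, 1), c(1, 0)),
                1 - cosineSimilarity(c(1, 1), c(0, 1))))
  expect_equal(medianThreatDistance("c", seeds, emb), d_c)
  # two-word cluster: median over the two word means
  d_d <- mean(c(1 - cosineSimilarity(c(1, 0.2), c(1, 0)),
                1 - cosineSimilarity(c(1, 0.2), c(0, 1))))
  expect_equal(medianThreatDistance(c("c", "d"), seeds, emb),
               median(c(d_c, d_d)))
  # identical embeddings -> zero distance
  emb2 <- mkEmb(a = c(1, 1), b = c(1, 1), c = c(1, 1))
  expect_equal(medianThreatDistance("c", c("a", "b"), emb2), 0)
  expect_error(medianThreatDistance(character(), seeds, emb), "empty")
  # duplicated seeds do not change the distance (deduplicated first)
  expect_equal(medianThreatDistance("c", c("a", "a", "b"), emb), d_c)
})

test_that("the threat report finds a planted peripheral threat blob", {
  for (s in 1:3) {
    g <- generateThreatEmbeddings(seed = s)
    words <- names(g$clusters)
    space <- pcaFit(embeddingVectors(g$emb), 4)
    rep1 <- suppressMessages(
      threatReport(space, words, g$threatWords[1:3], g$emb, k = 12,
                   fraction = 0.8, repeats = 50, seed = s))
    nw <- nearestThreatCluster(rep1)$words
    expect_gt(length(nw), 0)
    expect_true(all(nw %in% g$threatWords))
    # report table is sorted ascending and covers all clusters
    tb <- threatTable(rep1)
    expect_equal(nrow(tb), 12L)
    expect_false(is.unsorted(tb$medianDistance))
    # determinism
    rep2 <- suppressMessages(
      threatReport(space, words, g$threatWords[1:3], g$emb, k = 12,
                   fraction = 0.8, repeats = 50, seed = s))
    expect_identical(threatTable(rep1), threatTable(rep2))
  }
})

test_that("orthogonal seed geometry yields near-unit distances without error", {
  set.seed(47)
  n <- 40; dim <- 60
  v <- matrix(rnorm(n * dim), n, dim)
  v <- v / sqrt(rowSums(v^2))
  rownames(v) <- sprintf("w%02d", seq_len(n))
  emb <- EmbeddingTable(v)
  words <- rownames(v)
  space <- pcaFit(v, 3)
  rep1 <- threatReport(space, words, words[1:2], emb, k = 4,
                       fraction = 0.8, repeats = 20, seed = 1)
  tb <- threatTable(rep1)
  # random high-dimensional unit vectors are nearly orthogonal
  expect_true(all(abs(tb$medianDistance - 1) < 0.45))
})
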