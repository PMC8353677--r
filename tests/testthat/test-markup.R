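test_that("cosine similarity matches hand arithmetic and flags degenerate input", {
  v <- c(0.3, -1.2, 4)
  expect_equal(cosineSimilarity(v, v), 1.0)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0.0)
  # dot = 2 + 2 + 4 = 8, norms 3 and 3
  expect_equal(cosineSimilarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_equal(cosineSimilarity(c(1, 2, 2), c(2, 1, 2)),
               cosineSimilarity(c(2, 1, 2), c(1, 2, 2)))
  expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosineSimilarity(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("markup matrix holds per-cell cosine similarities at token midpoints", {
  emb <- mkEmb(sun = c(1, 0, 0), moon = c(0.8, 0.6, 0),
               rock = c(0, 0, 1), run = c(0.5, 0.5, sqrt(0.5)))
  vocab <- FeatureVocabulary(nouns = c("sun", "rock"), verbs = "run")
  stream <- TokenStream(c("moon", "sun", "run"),
                        t_start = c(0.5, 2.0, 3.5),
                        t_end = c(1.0, 2.5, 4.0), duration = 5)
  sm <- buildMarkupMatrix(stream, emb, vocab)
  expect_equal(dim(seriesMatrix(sm)), c(3L, 3L))
  expect_equal(wordTimes(sm), c(0.75, 2.25, 3.75))
  # brute-force cosine per cell
  v <- embeddingVectors(emb)
  for (i in seq_along(featureWords(vocab))) {
    for (j in seq_len(3)) {
      expect_equal(seriesMatrix(sm)[i, j],
                   cosineSimilarity(v[featureWords(vocab)[i], ],
                                    v[tokens(stream)$lemma[j], ]),
                   tolerance = 1e-12)
    }
  }
  # a token that IS a feature word scores exactly 1 on its own row
  expect_equal(seriesMatrix(sm)["sun", 2], 1.0)
  expect_equal(sum(seriesMatrix(sm)[, 2] == 1), 1L)
  expect_true(all(abs(seriesMatrix(sm)) <= 1))
})

test_that("markup is permutation-equivariant in the vocabulary", {
  emb <- randEmb(12, 6)
  words <- rownames(embeddingVectors(emb))
  stream <- TokenStream(words[7:12], t_start = 0:5, t_end = 0:5 + 0.4,
                        duration = 6)
  v1 <- FeatureVocabulary(nouns = words[1:3], verbs = words[4:6])
  v2 <- FeatureVocabulary(nouns = words[c(3, 1)], verbs = words[c(6, 4, 5)])
  m1 <- seriesMatrix(buildMarkupMatrix(stream, emb, v1))
  m2 <- seriesMatrix(buildMarkupMatrix(stream, emb, v2))
  expect_equal(m2, m1[c(3, 1, 6, 4, 5), ])
})

test_that("out-of-vocabulary lemmas error by default and can be skipped", {
  emb <- randEmb(5, 4)
  words <- rownames(embeddingVectors(emb))
  vocab <- FeatureVocabulary(nouns = words[1:2])
  stream <- TokenStream(c(words[3], "nonesuch", words[4]),
                        t_start = c(0, 1, 2), t_end = c(0.5, 1.5, 2.5),
                        duration = 3)
  expect_error(buildMarkupMatrix(stream, emb, vocab), "out-of-vocabulary")
  sm <- suppressMessages(buildMarkupMatrix(stream, emb, vocab, oov = "skip"))
  expect_equal(ncol(seriesMatrix(sm)), 2L)
})

test_that("row z-scoring follows the population-sd formula and is idempotent", {
  # population sd of (1,2,3) is sqrt(2/3)
  z <- zscoreRows(matrix(c(1, 2, 3), 1))
  expect_equal(as.numeric(z), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  set.seed(42)
  m <- matrix(rnorm(50), 5)
  z1 <- zscoreRows(m)
  expect_equal(rowMeans(z1), rep(0, 5), tolerance = 1e-10)
  expect_equal(sqrt(rowMeans(z1^2)), rep(1, 5), tolerance = 1e-10)
  expect_equal(zscoreRows(z1), z1, tolerance = 1e-10)
})

test_that("constant rows z-score to zeros with a warning", {
  m <- rbind(c(5, 5, 5), c(1, 2, 3))
  expect_warning(z <- zscoreRows(m), "constant")
  expect_equal(z[1, ], c(0, 0, 0))
  expect_false(all(z[2, ] == 0))
})

test_that("z-scoring a StimulusMatrix flags it standardized", {
  emb <- randEmb(8, 5)
  words <- rownames(embeddingVectors(emb))
  stream <- TokenStream(words[5:8], t_start = 0:3, t_end = 0:3 + 0.4,
                        duration = 4)
  sm <- buildMarkupMatrix(stream, emb,
                          FeatureVocabulary(nouns = words[1:4]))
  z <- zscoreRows(sm)
  expect_true(z@standardized)
  expect_equal(rowMeans(seriesMatrix(z)), rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("token stream and stimulus matrix validity catch malformed input", {
  expect_error(TokenStream("a", 1, 0.5), "t_start must be < t_end")
  expect_error(TokenStream(c("a", ""), c(0, 1), c(0.5, 1.5)), "empty lemma")
  expect_error(TokenStream("a", 0, 2, duration = 1), "duration")
  expect_error(EmbeddingTable(matrix(1:4, 2)), "rownames")
  expect_error(FeatureVocabulary(nouns = c("a", "b"), verbs = "a"),
               "duplicated")
})
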