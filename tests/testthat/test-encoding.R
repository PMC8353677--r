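test_that("detrending removes exact lines and normalizes residuals", {
  t <- seq_len(50)
  line <- 3 + 0.2 * t
  expect_warning(out <- detrendAndZscore(rbind(line)), "constant")
  expect_equal(as.numeric(out), rep(0, 50))
  set.seed(9)
  noise <- matrix(rnorm(200), 4)
  z <- detrendAndZscore(noise)
  expect_equal(rowMeans(z), rep(0, 4), tolerance = 1e-10)
  expect_equal(sqrt(rowMeans(z^2)), rep(1, 4), tolerance = 1e-10)
})

test_that("detrending a line plus sinusoid matches an independent lm fit", {
  t <- seq_len(80)
  y <- 2 - 0.05 * t + sin(2 * pi * t / 16)
  fit <- lm(y ~ t)
  oracle <- as.numeric(scale(resid(fit))) * sqrt(80 / (80 - 1))  # population sd
  z <- detrendAndZscore(rbind(y))
  expect_equal(as.numeric(z), oracle, tolerance = 1e-8)
})

test_that("ridge weights equal the dense closed form", {
  set.seed(11)
  X <- matrix(rnorm(150), 30, 5)
  Y <- matrix(rnorm(60), 30, 2)
  beta <- ridgeFit(X, Y, alpha = 2)
  oracle <- solve(crossprod(X) + 2 * diag(5), crossprod(X, Y))
  expect_equal(beta, oracle, tolerance = 1e-6)
})

test_that("ridge approaches OLS for tiny alpha and zero for huge alpha", {
  set.seed(12)
  X <- matrix(rnorm(36), 6, 6) + diag(6)  # well-conditioned square
  Y <- matrix(rnorm(12), 6, 2)
  bSmall <- ridgeFit(X, Y, 1e-12)
  expect_equal(bSmall, solve(X, Y), tolerance = 1e-6)
  bBig <- ridgeFit(X, Y, 1e12 * norm(X, "2")^2)
  expect_lt(max(abs(bBig)) / max(abs(bSmall)), 1e-6)
})

test_that("ridge matches a brute-force numeric minimizer of the objective", {
  set.seed(13)
  X <- matrix(rnorm(15), 5, 3)
  y <- rnorm(5)
  alpha <- 1.7
  loss <- function(b) sum((y - X %*% b)^2) + alpha * sum(b^2)
  num <- optim(rep(0, 3), loss, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))$par
  expect_equal(as.numeric(ridgeFit(X, cbind(y), alpha)), num,
               tolerance = 1e-5)
})

test_that("weight norm shrinks monotonically in alpha", {
  set.seed(14)
  X <- matrix(rnorm(40 * 12), 40, 12)
  Y <- matrix(rnorm(40 * 3), 40, 3)
  alphas <- c(0.1, 1, 10, 100, 1000)
  norms <- sapply(alphas, function(a) sum(ridgeFit(X, Y, a)^2))
  expect_true(all(diff(norms) < 0))
})

test_that("the p > t regime fits without error", {
  set.seed(15)
  X <- matrix(rnorm(50 * 400), 50, 400)   # far more features than samples
  Y <- matrix(rnorm(50 * 4), 50, 4)
  beta <- ridgeFit(X, Y, 10)
  expect_true(all(is.finite(beta)))
  expect_equal(dim(beta), c(400L, 4L))
  oracle <- solve(crossprod(X) + 10 * diag(400), crossprod(X, Y))
  expect_equal(beta, oracle, tolerance = 1e-6)
})

test_that("ridge validates its inputs", {
  expect_error(ridgeFit(matrix(1:6, 3), matrix(1:4, 2), 1), "sample axis")
  expect_error(ridgeFit(matrix(c(1, NA, 2, 3), 2), matrix(1:2, 2), 1),
               "non-finite")
  expect_error(ridgeFit(matrix(1:4, 2), matrix(1:2, 2), -1), "positive")
})

test_that("prediction is the exact linear product", {
  w <- matrix(0, 2, 3)
  S <- matrix(rnorm(15), 3, 5)
  expect_equal(predictBold(S, w), matrix(0, 2, 5))
  expect_equal(as.numeric(predictBold(rbind(c(1, 2, 3)), cbind(2))),
               c(2, 4, 6))
  expect_error(predictBold(S, matrix(1, 2, 4)), "predictors")
  # self-consistency: noiseless Y = Xb recovered at tiny alpha
  set.seed(16)
  Xt <- matrix(rnorm(60 * 8), 60, 8)
  b <- rnorm(8)
  y <- Xt %*% b
  bh <- ridgeFit(Xt, cbind(y), 1e-10)
  expect_gt(cor(as.numeric(Xt %*% bh), as.numeric(y)), 0.999)
})

test_that("per-voxel correlation reproduces the textbook formula", {
  a <- rbind(c(1, 2, 3, 4))
  expect_equal(as.numeric(perVoxelCorrelation(a, a)), 1)
  expect_equal(as.numeric(perVoxelCorrelation(a, -a)), -1)
  x <- c(1, 2, 4, 3); y <- c(2, 1, 5, 4)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(as.numeric(perVoxelCorrelation(rbind(x), rbind(y))), oracle)
  expect_warning(r0 <- perVoxelCorrelation(rbind(rep(1, 4)), rbind(y)),
                 "constant")
  expect_equal(as.numeric(r0), 0)
  expect_error(perVoxelCorrelation(a, rbind(1:3)), "equal shape")
})

test_that("alpha selection matches an exhaustive re-scoring of the grid", {
  alphas <- c(0.5, 2, 8, 30, 120)
  for (s in 1:4) {
    set.seed(100 + s)
    nT <- 60; p <- 10; m <- 8
    Xt <- matrix(rnorm(nT * p), nT, p)
    b <- matrix(rnorm(p * m), p, m)
    Yt <- Xt %*% b + matrix(rnorm(nT * m, sd = 3), nT, m)
    split <- splitScheme(45, 15, 36, 9, total = nT)
    sel <- selectAlpha(Xt, Yt, alphas, split, probeVoxels = m, seed = s)
    # brute force: refit every candidate with the generic solver and score
    itr <- 1:36; ival <- 37:45
    brute <- sapply(alphas, function(a) {
      bh <- ridgeFit(Xt[itr, ], Yt[itr, ], a)
      mean(sapply(seq_len(m), function(j) {
        cor(Xt[ival, ] %*% bh[, j], Yt[ival, j])
      }))
    })
    expect_equal(sel$alpha, alphas[which.max(brute)])
    expect_equal(sel$curve$meanR, brute, tolerance = 1e-10)
  }
})

test_that("degenerate searches behave: one candidate, noiseless data", {
  set.seed(21)
  Xt <- matrix(rnorm(50 * 6), 50, 6)
  Yt <- Xt %*% matrix(rnorm(12), 6, 2)
  split <- splitScheme(40, 10, 32, 8, total = 50)
  one <- selectAlpha(Xt, Yt, alphas = 7, split, probeVoxels = 2)
  expect_equal(one$alpha, 7)
  # noiseless: smallest alpha wins and the curve is maximal there
  sel <- selectAlpha(Xt, Yt, c(1e-6, 1, 100), split, probeVoxels = 2)
  expect_equal(sel$alpha, 1e-6)
  expect_equal(which.max(sel$curve$meanR), 1L)
})

test_that("split scheme arithmetic is validated", {
  s <- splitScheme(350, 140, 300, 50, total = 490)
  expect_equal(s@outerTrain + s@outerTest, 490L)
  expect_equal(s@innerTrain + s@innerVal, s@outerTrain)
  expect_error(splitScheme(350, 140, 300, 40), "innerTrain \\+ innerVal")
  expect_error(splitScheme(350, 100, 300, 50, total = 490),
               "does not match")
  d <- defaultSplit(490)
  expect_equal(c(d@outerTrain, d@outerTest, d@innerTrain, d@innerVal),
               c(350L, 140L, 300L, 50L))
})

test_that("global and per-voxel alpha comparison coincide when voxels are identical", {
  set.seed(23)
  nT <- 70; p <- 6
  Xt <- matrix(rnorm(nT * p), nT, p)
  y <- Xt %*% rnorm(p) + rnorm(nT)
  Yt <- cbind(y, y, y)
  split <- splitScheme(50, 20, 40, 10, total = nT)
  cmp <- compareAlphaModes(Xt, Yt, c(1, 10, 100), split)
  expect_equal(cmp$rGlobal, cmp$rPerVoxel)
  expect_equal(cmp$meanShift, 0)
  expect_length(cmp$rGlobal, 3)
  # single voxel: both modes reduce to the same scalar
  cmp1 <- compareAlphaModes(Xt, Yt[, 1, drop = FALSE], c(1, 10, 100), split)
  expect_equal(cmp1$rGlobal, cmp1$rPerVoxel)
  expect_length(cmp1$rGlobal, 1)
})

test_that("heterogeneous voxels yield two full histograms and a mean shift", {
  set.seed(24)
  nT <- 80; p <- 5; m <- 12
  Xt <- matrix(rnorm(nT * p), nT, p)
  noise <- seq(0.2, 6, length.out = m)
  Yt <- Xt %*% matrix(rnorm(p * m), p, m) +
    sapply(noise, function(s) rnorm(nT, sd = s))
  split <- splitScheme(60, 20, 48, 12, total = nT)
  cmp <- compareAlphaModes(Xt, Yt, c(0.5, 5, 50, 500), split)
  expect_length(cmp$rGlobal, m)
  expect_length(cmp$rPerVoxel, m)
  expect_true(is.finite(cmp$meanShift))
  expect_equal(cmp$meanShift, mean(cmp$rGlobal) - mean(cmp$rPerVoxel))
})

test_that("the fitted encoding model scores held-out data and stores the curve", {
  set.seed(25)
  cfg <- smallConfig(seed = 5)
  st <- generateSyntheticStudy(cfg)
  enc <- fitEncodingModel(st$design, st$bold, alphas = c(1, 10, 100),
                          probeVoxels = 20, seed = 5)
  expect_s4_class(enc, "EncodingResult")
  expect_equal(nrow(encodingWeights(enc)), cfg@nVoxels)
  expect_equal(ncol(encodingWeights(enc)),
               cfg@nFeatureWords * length(cfg@delays))
  expect_true(all(abs(perVoxelR(enc)) <= 1))
  expect_gt(mean(perVoxelR(enc)), 0.1)  # real signal is planted
  expect_equal(nrow(efficiencyCurve(enc)), 3L)
})
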