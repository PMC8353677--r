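## Voxel-wise ridge encoding model with nested, contiguous-in-time
## cross-validation for the regularization strength.

#' Construct a BoldMatrix
#'
#' @param values numeric matrix (voxels x samples).
#' @param coords integer matrix (voxels x 3) of voxel coordinates.
#' @param tr repetition time in seconds.
#' @return a [BoldMatrix-class].
#' @export
BoldMatrix <- function(values, coords, tr) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y", "z")
  new("BoldMatrix", values = as.matrix(values), coords = coords,
      tr = as.numeric(tr))
}

#' Construct a nested time split
#'
#' @param outerTrain,outerTest,innerTrain,innerVal positive sample counts;
#'   `innerTrain + innerVal` must equal `outerTrain`.
#' @param total optional total sample count to validate against
#'   (`outerTrain + outerTest == total`).
#' @return a [SplitScheme-class].
#' @examples
#' splitScheme(350, 140, 300, 50, total = 490)
#' @export
splitScheme <- function(outerTrain, outerTest, innerTrain, innerVal,
                        total = NULL) {
  s <- new("SplitScheme", outerTrain = as.integer(outerTrain),
           outerTest = as.integer(outerTest),
           innerTrain = as.integer(innerTrain),
           innerVal = as.integer(innerVal))
  if (!is.null(total) && s@outerTrain + s@outerTest != total)
    stop("outerTrain + outerTest (", s@outerTrain + s@outerTest,
         ") does not match the sample count (", total, ")")
  s
}

#' Default split for a run, scaled from the 350/140 + 300/50 scheme
#'
#' For a 490-sample run this is exactly 350/140 outer and 300/50 inner;
#' other run lengths get the same proportions (5/7 outer train, 6/7 of that
#' inner train).
#'
#' @param nSamples total number of TR samples.
#' @return a [SplitScheme-class].
#' @export
defaultSplit <- function(nSamples) {
  ot <- round(nSamples * 350 / 490)
  it <- round(ot * 300 / 350)
  splitScheme(ot, nSamples - ot, it, ot - it, total = nSamples)
}

#' Default regularization grid
#'
#' Log-spaced candidates covering the two search ranges 1..10 (10 points)
#' and 10..1000 (20 points), pooled into one curve.
#'
#' @return numeric vector of alpha candidates.
#' @export
defaultAlphaGrid <- function() {
  unique(c(10^seq(0, 1, length.out = 10), 10^seq(1, 3, length.out = 20)))
}

# Detrend rows (remove per-row best-fit line over the sample index) and
# z-score with the population-sd convention.
detrendRows <- function(m) {
  nt <- ncol(m)
  if (nt < 3) stop("need at least 3 samples to detrend")
  D <- cbind(1, seq_len(nt))
  coef <- m %*% D %*% solve(crossprod(D))
  m - coef %*% t(D)
}

#' @describeIn detrendAndZscore plain matrix method.
setMethod("detrendAndZscore", "matrix", function(x) {
  zscoreRowsMatrix(detrendRows(x))
})

#' @describeIn detrendAndZscore returns a [BoldMatrix-class] with
#'   detrended, z-scored voxel rows.
setMethod("detrendAndZscore", "BoldMatrix", function(x) {
  initialize(x, values = zscoreRowsMatrix(detrendRows(x@values)))
})

# Economy SVD of the [samples x predictors] design, for reuse across alpha
# candidates. With p > t only the first t singular directions exist.
ridgeSvd <- function(Xt) {
  sv <- svd(Xt, nu = min(dim(Xt)), nv = min(dim(Xt)))
  keep <- sv$d > max(dim(Xt)) * .Machine$double.eps * max(sv$d, 1)
  list(u = sv$u[, keep, drop = FALSE], d = sv$d[keep],
       v = sv$v[, keep, drop = FALSE])
}

# Closed-form ridge weights from an SVD: beta = V diag(d/(d^2+alpha)) U' Y,
# identical to (X'X + alpha I)^-1 X' Y. Returns [predictors x voxels].
ridgeFromSvd <- function(sv, Yt, alpha) {
  f <- sv$d / (sv$d^2 + alpha)
  sv$v %*% (f * crossprod(sv$u, Yt))
}

#' Ridge regression weights for all voxels
#'
#' Minimizes `||Y - X beta||^2 + alpha ||beta||^2` per voxel; the solution
#' equals the closed form `(X'X + alpha I)^-1 X' Y`, computed stably from
#' one economy SVD of the design that is shared across voxels. Handles the
#' p > t regime (more delayed features than time samples) without error.
#'
#' @param X a [DelayedDesign-class], [ResampledDesign-class] or a plain
#'   (samples x predictors) matrix.
#' @param Y a [BoldMatrix-class] or plain (samples x voxels) matrix sharing
#'   the sample axis with `X`.
#' @param alpha positive regularization strength.
#' @return weights: for matrix input, (predictors x voxels); for container
#'   input, (voxels x predictors) (one row per voxel, matching
#'   [EncodingResult-class]).
#' @export
ridgeFit <- function(X, Y, alpha) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be a positive number")
  containers <- !is.matrix(X)
  Xt <- if (is.matrix(X)) X else t(seriesMatrix(X))
  Yt <- if (is.matrix(Y)) Y else t(seriesMatrix(Y))
  if (!all(is.finite(Xt)) || !all(is.finite(Yt)))
    stop("non-finite values in design or BOLD")
  if (nrow(Xt) != nrow(Yt))
    stop("design and BOLD disagree on the sample axis (",
         nrow(Xt), " vs ", nrow(Yt), ")")
  beta <- ridgeFromSvd(ridgeSvd(Xt), Yt, alpha)
  if (containers) t(beta) else beta
}

#' Predict BOLD from encoding weights
#'
#' The linear prediction `R'_jt = sum_i beta_ji S_it`, an exact matrix
#' product of the weights with the design.
#'
#' @param X a [DelayedDesign-class]/[ResampledDesign-class] or plain
#'   (predictors x samples) matrix.
#' @param weights numeric matrix (voxels x predictors).
#' @return predicted BOLD (voxels x samples).
#' @export
predictBold <- function(X, weights) {
  S <- if (is.matrix(X)) X else seriesMatrix(X)
  if (ncol(weights) != nrow(S))
    stop("weights have ", ncol(weights), " predictors but design has ",
         nrow(S), " rows")
  weights %*% S
}

#' Per-voxel Pearson correlation between predicted and actual BOLD
#'
#' @param pred,actual numeric matrices (voxels x samples) of equal shape.
#' @return numeric vector of correlations in \[-1, 1\]; constant series
#'   yield 0 with a warning.
#' @export
perVoxelCorrelation <- function(pred, actual) {
  if (!all(dim(pred) == dim(actual)))
    stop("prediction and actual BOLD must have equal shape")
  rowPearson(pred, actual)
}

# Efficiency of each alpha candidate: fit on the inner training block,
# score mean held-out correlation on the inner validation block over a
# probe voxel subset. Returns the per-voxel validation correlation matrix
# [alphas x probe voxels] so callers can also pick per-voxel winners.
innerValidationR <- function(Xt, Yt, alphas, split, probe) {
  itr <- seq_len(split@innerTrain)
  ival <- split@innerTrain + seq_len(split@innerVal)
  sv <- ridgeSvd(Xt[itr, , drop = FALSE])
  Yp <- Yt[, probe, drop = FALSE]
  utY <- crossprod(sv$u, Yp[itr, , drop = FALSE])
  xv <- Xt[ival, , drop = FALSE] %*% sv$v
  Yval <- t(Yp[ival, , drop = FALSE])
  out <- matrix(NA_real_, length(alphas), length(probe))
  for (i in seq_along(alphas)) {
    f <- sv$d / (sv$d^2 + alphas[i])
    pred <- t(xv %*% (f * utY))
    if (!all(is.finite(pred))) {
      message("alpha = ", alphas[i], " produced non-finite weights; scored -Inf")
      out[i, ] <- -Inf
    } else {
      out[i, ] <- suppressWarnings(rowPearson(pred, Yval))
    }
  }
  out
}

#' Select the ridge regularizer by nested cross-validation
#'
#' For each candidate alpha, weights are fitted on the inner training block
#' and scored by the mean held-out correlation on the inner validation
#' block over a random probe subset of voxels; the candidate with the best
#' mean correlation wins. The full efficiency curve is returned alongside.
#'
#' @param X design ([DelayedDesign-class] or (samples x predictors)
#'   matrix).
#' @param Y BOLD ([BoldMatrix-class] or (samples x voxels) matrix).
#' @param alphas numeric candidate grid (default [defaultAlphaGrid()]).
#' @param split a [SplitScheme-class] consistent with the sample count.
#' @param probeVoxels number of probe voxels (default 500, capped at the
#'   voxel count).
#' @param seed RNG seed for the probe draw.
#' @return list with `alpha` (the winner), `curve` (data.frame alpha /
#'   meanR) and `probe` (the probe voxel indices).
#' @export
selectAlpha <- function(X, Y, alphas = defaultAlphaGrid(), split,
                        probeVoxels = 500, seed = 1) {
  Xt <- if (is.matrix(X)) X else t(seriesMatrix(X))
  Yt <- if (is.matrix(Y)) Y else t(seriesMatrix(Y))
  if (any(alphas <= 0)) stop("alpha candidates must be positive")
  if (split@outerTrain + split@outerTest != nrow(Xt))
    stop("split does not match the sample count")
  nv <- ncol(Yt)
  probe <- if (probeVoxels >= nv) seq_len(nv) else
    withSeed(seed, sort(sample.int(nv, probeVoxels)))
  rmat <- innerValidationR(Xt, Yt, alphas, split, probe)
  meanR <- rowMeans(rmat)
  best <- which.max(meanR)
  list(alpha = alphas[best],
       curve = data.frame(alpha = alphas, meanR = meanR),
       probe = probe)
}

#' Fit the full voxel-wise encoding model
#'
#' Selects the regularizer with [selectAlpha()], fits weights on the outer
#' training block, and scores the held-out correlation of every voxel on
#' the outer test block. The stored weight matrix is then refit on all
#' samples with the winning alpha (`finalFit = "all"`, the default) or kept
#' as the training-block fit (`finalFit = "train"`).
#'
#' @inheritParams selectAlpha
#' @param finalFit `"all"` or `"train"`.
#' @return an [EncodingResult-class].
#' @export
fitEncodingModel <- function(X, Y, alphas = defaultAlphaGrid(), split = NULL,
                             probeVoxels = 500, seed = 1,
                             finalFit = c("all", "train")) {
  finalFit <- match.arg(finalFit)
  Xt <- if (is.matrix(X)) X else t(seriesMatrix(X))
  Yt <- if (is.matrix(Y)) Y else t(seriesMatrix(Y))
  if (is.null(split)) split <- defaultSplit(nrow(Xt))
  sel <- selectAlpha(Xt, Yt, alphas, split, probeVoxels, seed)
  otr <- seq_len(split@outerTrain)
  ote <- split@outerTrain + seq_len(split@outerTest)
  svTrain <- ridgeSvd(Xt[otr, , drop = FALSE])
  betaTrain <- ridgeFromSvd(svTrain, Yt[otr, , drop = FALSE], sel$alpha)
  predTest <- t(Xt[ote, , drop = FALSE] %*% betaTrain)
  r <- suppressWarnings(rowPearson(predTest, t(Yt[ote, , drop = FALSE])))
  weights <- if (finalFit == "all") {
    t(ridgeFromSvd(ridgeSvd(Xt), Yt, sel$alpha))
  } else {
    t(betaTrain)
  }
  nd <- if (is.matrix(X)) 1L else length(X@delays)
  nf <- if (is.matrix(X)) ncol(Xt) else X@nFeatures
  new("EncodingResult", weights = weights, alpha = sel$alpha,
      perVoxelR = as.numeric(r), split = split,
      efficiencyCurve = sel$curve,
      delays = if (is.matrix(X)) 0 else X@delays,
      nFeatures = as.integer(nf), finalFit = finalFit)
}

#' Compare one global alpha against per-voxel alphas
#'
#' Fits, for every voxel, (i) weights under the single alpha that maximizes
#' the mean inner-validation correlation across voxels and (ii) weights
#' under that voxel's own best alpha, and scores both on the outer test
#' block. The two held-out correlation distributions are returned with the
#' difference of their means (global minus per-voxel).
#'
#' @inheritParams selectAlpha
#' @return list with `rGlobal`, `rPerVoxel` (held-out correlations per
#'   voxel), `globalAlpha`, `perVoxelAlpha`, and `meanShift =
#'   mean(rGlobal) - mean(rPerVoxel)`.
#' @export
compareAlphaModes <- function(X, Y, alphas = defaultAlphaGrid(), split,
                              probeVoxels = Inf, seed = 1) {
  Xt <- if (is.matrix(X)) X else t(seriesMatrix(X))
  Yt <- if (is.matrix(Y)) Y else t(seriesMatrix(Y))
  nv <- ncol(Yt)
  probe <- if (!is.finite(probeVoxels) || probeVoxels >= nv) seq_len(nv) else
    withSeed(seed, sort(sample.int(nv, probeVoxels)))
  rmat <- innerValidationR(Xt, Yt, alphas, split, probe)
  globalAlpha <- alphas[which.max(rowMeans(rmat))]
  pvAlpha <- alphas[apply(rmat, 2, which.max)]
  otr <- seq_len(split@outerTrain)
  ote <- split@outerTrain + seq_len(split@outerTest)
  sv <- ridgeSvd(Xt[otr, , drop = FALSE])
  Yp <- Yt[, probe, drop = FALSE]
  utY <- crossprod(sv$u, Yp[otr, , drop = FALSE])
  xte <- Xt[ote, , drop = FALSE] %*% sv$v
  Ytest <- t(Yp[ote, , drop = FALSE])
  heldOutR <- function(alphaPerVoxel) {
    pred <- matrix(0, length(probe), length(ote))
    for (a in unique(alphaPerVoxel)) {
      grp <- which(alphaPerVoxel == a)
      f <- sv$d / (sv$d^2 + a)
      pred[grp, ] <- t(xte %*% (f * utY[, grp, drop = FALSE]))
    }
    suppressWarnings(rowPearson(pred, Ytest))
  }
  rGlobal <- heldOutR(rep(globalAlpha, length(probe)))
  rPerVoxel <- heldOutR(pvAlpha)
  list(rGlobal = rGlobal, rPerVoxel = rPerVoxel,
       globalAlpha = globalAlpha, perVoxelAlpha = pvAlpha,
       meanShift = mean(rGlobal) - mean(rPerVoxel))
}
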