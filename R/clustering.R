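## Semantic clustering: delay averaging, voxel selection, PCA, k-means over
## feature words, and voxel localization of the clusters.

#' Average encoding weights over haemodynamic delays
#'
#' Collapses the delayed copies of each feature back to one weight per
#' feature by averaging: entry (j, i) of the result is the mean of the
#' `nDelays` delayed-copy weights of feature i in voxel j. Columns must be
#' feature-major (the [delayEmbed()] ordering). This is a post-hoc
#' reduction of the fitted weights; no model is re-fit.
#'
#' @param weights (voxels x features * nDelays) matrix or an
#'   [EncodingResult-class].
#' @param nDelays number of delayed copies per feature (taken from the
#'   result object when omitted).
#' @return numeric matrix (voxels x features).
#' @export
averageDelays <- function(weights, nDelays = NULL) {
  if (is(weights, "EncodingResult")) {
    if (is.null(nDelays)) nDelays <- length(weights@delays)
    weights <- encodingWeights(weights)
  }
  nDelays <- as.integer(nDelays)
  p <- ncol(weights)
  if (p %% nDelays != 0)
    stop(p, " columns not divisible by ", nDelays, " delays")
  nf <- p %/% nDelays
  # feature-major column order: delay index varies fastest
  agg <- kronecker(diag(nf), matrix(1 / nDelays, nDelays, 1))
  out <- weights %*% agg
  cn <- colnames(weights)
  if (!is.null(cn)) colnames(out) <- sub("@.*$", "", cn[seq(1, p, by = nDelays)])
  out
}

#' Select the best-predicted voxels
#'
#' @param perVoxelR numeric vector of per-voxel prediction correlations.
#' @param n number of voxels to keep.
#' @return sorted integer indices of the `n` largest correlations; ties are
#'   broken toward the lower index.
#' @export
selectTopVoxels <- function(perVoxelR, n) {
  if (n <= 0) stop("n must be positive")
  if (n > length(perVoxelR)) stop("n exceeds the voxel count")
  sort(order(-perVoxelR, seq_along(perVoxelR))[seq_len(n)])
}

#' Principal-component space of a weight matrix
#'
#' Mean-centered (unscaled) PCA of `W` with voxels as observations and
#' feature words as variables. Components are sign-fixed so the largest-
#' magnitude loading of each component is positive, making runs
#' comparable.
#'
#' @param W numeric matrix (voxels x features), typically the delay-
#'   averaged weights restricted to the best-predicted voxels.
#' @param nComponents number of components to retain (default 4).
#' @return a [PcaSpace-class].
#' @export
pcaFit <- function(W, nComponents = 4) {
  if (!all(is.finite(W))) stop("W must be finite")
  if (nrow(W) <= nComponents)
    stop("need more observations (", nrow(W), ") than components (",
         nComponents, ")")
  pc <- stats::prcomp(W, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(dim(W)) * .Machine$double.eps * pc$sdev[1])
  if (rank < nComponents)
    stop("requested ", nComponents, " components but the matrix has rank ",
         rank)
  load <- pc$rotation[, seq_len(nComponents), drop = FALSE]
  sc <- pc$x[, seq_len(nComponents), drop = FALSE]
  flip <- apply(load, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, "*")
  sc <- sweep(sc, 2, flip, "*")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  new("PcaSpace", scores = sc, loadings = load,
      explainedVariance = ev[seq_len(nComponents)],
      center = pc$center)
}

# k-means++ seeding: first center uniform, then points weighted by squared
# distance to the nearest chosen center. RNG state is the caller's.
kmeansPlusPlusInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- sqDistToCenters(x, centers[1, , drop = FALSE])[, 1]
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, sqDistToCenters(x, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

# Lloyd iterations with farthest-point reseeding of empty clusters.
lloyd <- function(x, centers, maxIter = 100, tol = 1e-10) {
  k <- nrow(centers)
  labels <- integer(nrow(x))
  inertia <- Inf
  for (it in seq_len(maxIter)) {
    d2 <- sqDistToCenters(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(labels == j)) {
        # re-seed empty cluster from the point farthest from its center
        far <- which.max(d2[cbind(seq_len(nrow(x)), labels)])
        warning("empty cluster ", j, " re-seeded from the farthest point")
        centers[j, ] <- x[far, ]
        labels[far] <- j
        d2 <- sqDistToCenters(x, centers)
      }
    }
    newInertia <- sum(d2[cbind(seq_len(nrow(x)), labels)])
    for (j in seq_len(k)) centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    if (inertia - newInertia < tol * max(1, inertia)) {
      inertia <- newInertia
      break
    }
    inertia <- newInertia
  }
  d2 <- sqDistToCenters(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  list(labels = labels, centers = centers, inertia = inertia)
}

#' Cluster feature words in component space with k-means
#'
#' Lloyd iterations from a k-means++ initialization under a fixed seed;
#' the within-cluster sum of squares is non-increasing across iterations
#' and empty clusters are re-seeded from the farthest point. Feature words
#' are represented by their loading coordinates in the PCA space.
#'
#' @param space a [PcaSpace-class] (its loadings are clustered) or a plain
#'   (points x dims) matrix with rownames.
#' @param k number of clusters (default 15).
#' @param seed integer RNG seed; fixed seed gives bit-identical labels.
#' @return a [ClusterModel-class].
#' @export
kmeansFeatures <- function(space, k = 15, seed = 1) {
  x <- if (is(space, "PcaSpace")) pcaLoadings(space) else as.matrix(space)
  if (k > nrow(x)) stop("k exceeds the number of points")
  fit <- withSeed(seed, {
    init <- kmeansPlusPlusInit(x, k)
    lloyd(x, init)
  })
  labels <- as.integer(fit$labels)
  names(labels) <- rownames(x)
  new("ClusterModel", labels = labels, centers = fit$centers,
      k = as.integer(k), seed = as.integer(seed), inertia = fit$inertia)
}

#' Localize semantic clusters to voxels
#'
#' For every cluster, voxels are scored by the mean (delay-averaged)
#' encoding weight over the cluster's feature words, and only the
#' top-scoring fraction is kept — the voxels where that semantic category
#' loads most strongly.
#'
#' @param weightsAvg numeric matrix (voxels x features), delay-averaged
#'   weights over the selected voxel set.
#' @param model a [ClusterModel-class] whose labels are named by the
#'   columns of `weightsAvg` (or align positionally).
#' @param coords integer matrix (voxels x 3) of the same voxel set.
#' @param topFraction fraction of voxels kept per cluster (default 0.05).
#' @return a [ClusterLocalization-class].
#' @export
localizeClusters <- function(weightsAvg, model, coords, topFraction = 0.05) {
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must lie in (0, 1]")
  if (nrow(coords) != nrow(weightsAvg))
    stop("coords and weightsAvg disagree on the voxel count")
  labels <- clusterLabels(model)
  if (!is.null(names(labels)) && !is.null(colnames(weightsAvg))) {
    idx <- match(names(labels), colnames(weightsAvg))
    if (anyNA(idx)) stop("cluster features absent from the weight matrix")
  } else {
    if (length(labels) != ncol(weightsAvg))
      stop("label count does not match the feature count")
    idx <- seq_along(labels)
  }
  nKeep <- max(1L, ceiling(topFraction * nrow(weightsAvg)))
  rows <- vector("list", model@k)
  for (cl in seq_len(model@k)) {
    feats <- idx[labels == cl]
    if (length(feats) == 0) {
      warning("cluster ", cl, " is empty; no localization")
      next
    }
    score <- rowMeans(weightsAvg[, feats, drop = FALSE])
    top <- sort(order(-score, seq_along(score))[seq_len(nKeep)])
    rows[[cl]] <- data.frame(cluster = cl, voxel = top,
                             x = coords[top, 1], y = coords[top, 2],
                             z = coords[top, 3], score = score[top])
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(cluster = integer(), voxel = integer(),
                      x = integer(), y = integer(), z = integer(),
                      score = numeric())
  rownames(tab) <- NULL
  new("ClusterLocalization", table = tab, topFraction = topFraction)
}
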