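## Individual-level threat-semantics analysis: peripheral-point selection,
## single-linkage clustering in component space, and median embedding
## distance of each cluster to a set of threat seed words.

#' Validate and deduplicate a threat seed list
#'
#' @param words character seed words (whitespace-separated entries are
#'   split into individual words).
#' @param emb an [EmbeddingTable-class] that must resolve every seed.
#' @return character vector of unique, resolvable seed words.
#' @export
threatSeedList <- function(words, emb) {
  words <- unlist(strsplit(words, "[[:space:]]+"))
  words <- words[nzchar(words)]
  if (length(words) == 0) stop("empty seed list")
  if (anyDuplicated(words)) {
    message("removing ", sum(duplicated(words)), " duplicate seed word(s)")
    words <- unique(words)
  }
  lookupEmbeddings(words, emb, oov = "error")
  words
}

#' Select the peripheral points of a component space
#'
#' Repeatedly draws a random subset of the points (a `fraction` of them),
#' ranks every drawn point by its distance from the subset centroid, and
#' averages those ranks across draws. Points whose mean rank falls in the
#' top `1 - fraction` tail — the points consistently most distant from the
#' center — are returned. Deterministic given `seed`.
#'
#' @param space a [PcaSpace-class] or a plain (points x dims) matrix.
#' @param fraction subset fraction per draw, in (0, 1); default 0.8.
#' @param repeats number of random draws (default 100).
#' @param seed integer RNG seed.
#' @param which for a [PcaSpace-class], whether points are the `"scores"`
#'   rows (default) or the `"loadings"` rows (feature words).
#' @return sorted integer indices of the selected points.
#' @export
selectPeripheralPoints <- function(space, fraction = 0.8, repeats = 100,
                                   seed = 1, which = c("scores", "loadings")) {
  which <- match.arg(which)
  x <- threatPoints(space, which)
  n <- nrow(x)
  if (n < 5) stop("need at least 5 points")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  if (repeats < 1) stop("repeats must be >= 1")
  m <- min(n, max(2L, floor(fraction * n)))
  rankSum <- numeric(n)
  drawCount <- numeric(n)
  withSeed(seed, {
    for (rep in seq_len(repeats)) {
      idx <- sample.int(n, m)
      sub <- x[idx, , drop = FALSE]
      d <- sqrt(rowSums(sweep(sub, 2, colMeans(sub))^2))
      rankSum[idx] <- rankSum[idx] + rank(d, ties.method = "average")
      drawCount[idx] <- drawCount[idx] + 1
    }
  })
  meanRank <- ifelse(drawCount > 0, rankSum / drawCount, -Inf)
  nSel <- max(1L, ceiling((1 - fraction) * n))
  sort(order(-meanRank, seq_len(n))[seq_len(nSel)])
}

threatPoints <- function(space, which = "scores") {
  if (is(space, "PcaSpace")) {
    if (which == "loadings") pcaLoadings(space) else pcaScores(space)
  } else {
    as.matrix(space)
  }
}

#' Single-linkage ("closest neighbor") clustering of points
#'
#' Agglomerative single-linkage hierarchy cut at `k` clusters; labels are
#' deterministic for fixed input.
#'
#' @param points numeric matrix (points x dims); duplicates allowed.
#' @param k number of clusters (default 12).
#' @return integer cluster labels in 1..k, named by the point rownames.
#' @export
nearestNeighborClusters <- function(points, k = 12) {
  points <- as.matrix(points)
  if (k > nrow(points)) stop("k exceeds the number of points")
  hc <- stats::hclust(stats::dist(points), method = "single")
  labels <- stats::cutree(hc, k = k)
  storage.mode(labels) <- "integer"
  labels
}

#' Median embedding distance of a word cluster to the threat seeds
#'
#' For each cluster word, the mean distance of its embedding to all seed
#' words is computed; the cluster's distance is the median of those means.
#'
#' @param clusterWords character, the member words of one cluster.
#' @param seeds character seed words (see [threatSeedList()]).
#' @param emb an [EmbeddingTable-class] resolving all words.
#' @param metric `"cosine"` (1 - cosine similarity, the default) or
#'   `"euclidean"`.
#' @return numeric(1) median distance, >= 0.
#' @export
medianThreatDistance <- function(clusterWords, seeds, emb,
                                 metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  if (length(clusterWords) == 0) stop("empty cluster")
  seeds <- unique(seeds)
  v <- embeddingVectors(emb)
  cw <- v[lookupEmbeddings(clusterWords, emb, "error"), , drop = FALSE]
  sw <- v[lookupEmbeddings(seeds, emb, "error"), , drop = FALSE]
  if (metric == "cosine") {
    d <- 1 - unitRows(cw) %*% t(unitRows(sw))
    d <- pmax(d, 0)
  } else {
    d <- sqrt(sqDistToCenters(cw, sw))
  }
  stats::median(rowMeans(d))
}

#' Individual threat-semantics report
#'
#' Composes the peripheral-point selection, single-linkage clustering into
#' `k` clusters, and per-cluster median embedding distance to the threat
#' seed words. The cluster attaining the minimal median distance is
#' reported as the threat cluster; the table lists all clusters sorted by
#' distance ascending.
#'
#' @param space a [PcaSpace-class] or (points x dims) matrix.
#' @param words character labels of the points (the stimulus words they
#'   represent), one per row of the point matrix.
#' @param seeds character threat seed words.
#' @param emb an [EmbeddingTable-class].
#' @param k number of clusters (default 12).
#' @param fraction peripheral-selection subset fraction (default 0.8).
#' @param repeats resampling repeats (default 100).
#' @param seed integer RNG seed.
#' @param metric distance metric, `"cosine"` or `"euclidean"`.
#' @param which point source for a [PcaSpace-class] (`"scores"` or
#'   `"loadings"`).
#' @return a [ThreatReport-class].
#' @export
threatReport <- function(space, words, seeds, emb, k = 12, fraction = 0.8,
                         repeats = 100, seed = 1,
                         metric = c("cosine", "euclidean"),
                         which = c("scores", "loadings")) {
  metric <- match.arg(metric)
  which <- match.arg(which)
  x <- threatPoints(space, which)
  if (length(words) != nrow(x))
    stop("words must label every point (", length(words), " vs ",
         nrow(x), ")")
  seeds <- threatSeedList(seeds, emb)
  sel <- selectPeripheralPoints(x, fraction, repeats, seed)
  labels <- nearestNeighborClusters(x[sel, , drop = FALSE], k)
  selWords <- words[sel]
  med <- vapply(seq_len(k), function(cl) {
    medianThreatDistance(selWords[labels == cl], seeds, emb, metric)
  }, numeric(1))
  memberWords <- vapply(seq_len(k), function(cl) {
    paste(selWords[labels == cl], collapse = " ")
  }, character(1))
  sizes <- tabulate(labels, nbins = k)
  ord <- order(med, seq_len(k))
  tab <- data.frame(cluster = seq_len(k)[ord], medianDistance = med[ord],
                    size = sizes[ord], words = memberWords[ord])
  rownames(tab) <- NULL
  nearest <- tab$cluster[1]
  new("ThreatReport", table = tab, nearestCluster = as.integer(nearest),
      nearestWords = strsplit(tab$words[1], " ")[[1]],
      metadata = list(k = k, fraction = fraction, repeats = repeats,
                      seed = seed, metric = metric, seeds = seeds,
                      selected = sel))
}
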