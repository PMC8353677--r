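## Synthetic study generator: planted-cluster embeddings, a jittered word
## stream with a topic schedule, and BOLD built from known sparse weights
## through the delayed design — every pipeline stage gets a recovery
## oracle.

#' Configuration of the synthetic study
#'
#' Defaults mirror the scales of the target study: 300-dimensional
#' embeddings, 997 feature words, TR 1.01 s, delays 2/4/6/8 s and a run
#' long enough for 490 TR samples. The voxel count defaults to 2000 so the
#' full pipeline runs in minutes; noise defaults to the signal's own
#' standard deviation (SNR 1).
#'
#' @param nVocabWords vocabulary size (feature words are its head).
#' @param embeddingDim embedding dimensionality.
#' @param nPlantedClusters number of planted semantic clusters.
#' @param nFeatureWords number of feature words (nouns + verbs).
#' @param runDuration run length in seconds.
#' @param wordRate speech rate in words per second.
#' @param tr repetition time in seconds.
#' @param delays haemodynamic delays in seconds.
#' @param nVoxels number of masked voxels.
#' @param trueWeightSparsity fraction of a voxel's within-cluster features
#'   that carry non-zero true weight.
#' @param noiseSd noise sd relative to each voxel's signal sd.
#' @param seed master RNG seed.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nVocabWords = 1200, embeddingDim = 300,
                            nPlantedClusters = 5, nFeatureWords = 997,
                            runDuration = 490 * 1.01, wordRate = 2.5,
                            tr = 1.01, delays = c(2, 4, 6, 8),
                            nVoxels = 2000, trueWeightSparsity = 1,
                            noiseSd = 1, seed = 1) {
  new("SyntheticConfig", nVocabWords = as.integer(nVocabWords),
      embeddingDim = as.integer(embeddingDim),
      nPlantedClusters = as.integer(nPlantedClusters),
      nFeatureWords = as.integer(nFeatureWords),
      runDuration = as.numeric(runDuration),
      wordRate = as.numeric(wordRate), tr = as.numeric(tr),
      delays = as.numeric(delays), nVoxels = as.integer(nVoxels),
      trueWeightSparsity = as.numeric(trueWeightSparsity),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

# Draw k centroids on the unit sphere with pairwise |cosine| <= maxCos.
drawSeparatedCentroids <- function(k, dim, maxCos = 0.5, maxTries = 500) {
  cents <- matrix(NA_real_, k, dim)
  for (j in seq_len(k)) {
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      cand <- stats::rnorm(dim)
      cand <- cand / sqrt(sum(cand^2))
      if (j == 1 ||
          max(abs(cents[seq_len(j - 1), , drop = FALSE] %*% cand)) <= maxCos) {
        cents[j, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place ", k, " centroids with pairwise |cos| <= ",
           maxCos, " in dimension ", dim)
  }
  cents
}

#' Generate a planted-cluster embedding table
#'
#' Cluster centroids are drawn on the unit sphere with an enforced minimum
#' pairwise angle (|cos| <= 0.5); member vectors are the centroid plus a
#' small isotropic perturbation, renormalized, so within-cluster cosine
#' similarity clearly exceeds between-cluster similarity. Words are
#' assigned to clusters cyclically, so the feature-word head of the
#' vocabulary covers every cluster. Deterministic given the config seed.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return list with `emb` (an [EmbeddingTable-class]) and `clusters`
#'   (named integer planted cluster per word).
#' @export
generateEmbeddings <- function(cfg) {
  k <- cfg@nPlantedClusters
  n <- cfg@nVocabWords
  dim <- cfg@embeddingDim
  sigma <- 0.55 / sqrt(dim)
  withSeed(cfg@seed, {
    cents <- drawSeparatedCentroids(k, dim)
    clusters <- rep_len(seq_len(k), n)
    v <- cents[clusters, , drop = FALSE] +
      matrix(stats::rnorm(n * dim, sd = sigma), n, dim)
    v <- unitRows(v)
    words <- sprintf("word%05d", seq_len(n))
    rownames(v) <- words
    names(clusters) <- words
    list(emb = EmbeddingTable(v), clusters = clusters)
  })
}

#' Feature vocabulary of a synthetic study
#'
#' The head of the synthetic vocabulary, split into a "noun" half and a
#' "verb" half (for 997 feature words: 498 + 499), order preserved.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param emb the embedding list from [generateEmbeddings()].
#' @return a [FeatureVocabulary-class].
#' @export
syntheticVocabulary <- function(cfg, emb) {
  feats <- rownames(embeddingVectors(emb$emb))[seq_len(cfg@nFeatureWords)]
  nn <- floor(length(feats) / 2)
  FeatureVocabulary(nouns = feats[seq_len(nn)], verbs = feats[-seq_len(nn)])
}

#' Generate a timed word stream with a planted topic schedule
#'
#' Word onsets follow a jittered regular grid at the configured speech
#' rate; durations stay inside the inter-onset gaps. The run is divided
#' into `nPlantedClusters` contiguous blocks emulating thematic text
#' groups: within block b, lemmas are drawn from planted cluster b with
#' probability 0.7 and uniformly from the whole vocabulary otherwise.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param emb the embedding list from [generateEmbeddings()].
#' @return a [TokenStream-class] with duration `cfg@runDuration`.
#' @export
generateTokenStream <- function(cfg, emb) {
  nTok <- max(1L, floor(cfg@wordRate * cfg@runDuration))
  gap <- 1 / cfg@wordRate
  clusters <- emb$clusters
  words <- names(clusters)
  k <- cfg@nPlantedClusters
  withSeed(cfg@seed + 1L, {
    onset <- (seq_len(nTok) - 1) * gap + stats::runif(nTok, 0, 0.3 * gap)
    dur <- 0.5 * gap
    block <- pmin(k, 1L + ((seq_len(nTok) - 1L) * k) %/% nTok)
    lemma <- character(nTok)
    for (b in seq_len(k)) {
      inB <- which(block == b)
      own <- words[clusters == b]
      fromTopic <- stats::runif(length(inB)) < 0.7
      lemma[inB[fromTopic]] <- sample(own, sum(fromTopic), replace = TRUE)
      lemma[inB[!fromTopic]] <- sample(words, sum(!fromTopic), replace = TRUE)
    }
    TokenStream(lemma, onset, onset + dur, duration = cfg@runDuration)
  })
}

#' Generate synthetic BOLD from a delayed design with known weights
#'
#' True feature-level weights are sparse and block-structured: voxels are
#' divided into contiguous blocks, one per planted cluster, and a voxel
#' loads (weight 1, thinned by `trueWeightSparsity`) exactly on the
#' feature words of its cluster. The delayed copies of each feature are
#' scaled by the canonical HRF evaluated at the corresponding delay, the
#' signal is the product of these delayed weights with the design, and
#' white Gaussian noise of sd `noiseSd` times each voxel's signal sd is
#' added. Voxel coordinates are laid out x-fastest on a compact 3-D grid,
#' so planted blocks are contiguous in scan order.
#'
#' @param design a [DelayedDesign-class] built from the synthetic markup.
#' @param cfg a [SyntheticConfig-class].
#' @param featureClusters integer planted cluster of each (undelayed)
#'   feature, length `design@nFeatures`.
#' @return list with `bold` (a [BoldMatrix-class]) and `truth` (a
#'   [GroundTruth-class]).
#' @export
generateBold <- function(design, cfg, featureClusters) {
  nf <- design@nFeatures
  nd <- length(design@delays)
  if (length(featureClusters) != nf)
    stop("featureClusters must have one entry per feature")
  k <- cfg@nPlantedClusters
  nv <- cfg@nVoxels
  voxelCluster <- rep(seq_len(k), each = ceiling(nv / k))[seq_len(nv)]
  hrf <- canonicalHrf(tr = 0.1)
  h <- hrfAt(hrf, design@delays)
  if (all(h == 0)) h <- rep(1, nd)
  withSeed(cfg@seed + 2L, {
    W <- matrix(0, nv, nf)
    for (b in seq_len(k)) {
      feats <- which(featureClusters == b)
      vox <- which(voxelCluster == b)
      on <- matrix(stats::runif(length(vox) * length(feats)) <=
                     cfg@trueWeightSparsity, length(vox), length(feats))
      W[vox, feats] <- on * 1
    }
    # spread feature weights over delayed copies with HRF amplitudes
    Bd <- W[, rep(seq_len(nf), each = nd), drop = FALSE] *
      rep(rep(h, times = nf), each = nv)
    signal <- Bd %*% seriesMatrix(design)
    s <- rowPopSd(signal)
    ref <- if (any(s > 0)) mean(s[s > 0]) else 1
    s[s <= 0] <- ref
    noise <- matrix(stats::rnorm(length(signal)), nrow(signal)) *
      (cfg@noiseSd * s)
    Y <- signal + noise
    side <- ceiling(nv^(1 / 3))
    dims <- c(side, side, ceiling(nv / side^2))
    coords <- arrayInd(seq_len(nv), dims)
    truth <- new("GroundTruth", trueWeights = W,
                 wordCluster = integer(0),
                 voxelCluster = as.integer(voxelCluster),
                 delayAmplitudes = h, noiseSd = cfg@noiseSd)
    list(bold = BoldMatrix(Y, coords, design@tr), truth = truth)
  })
}

#' Generate a complete synthetic study
#'
#' Runs the whole generator: planted embeddings, feature vocabulary, timed
#' token stream, z-scored markup matrix, Lanczos-resampled and delay-
#' embedded design, and BOLD with planted ground truth. Bit-reproducible
#' given `cfg@seed`.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param lanczosA Lanczos window parameter (default 3).
#' @return list with components `cfg`, `emb`, `clusters`, `vocab`,
#'   `stream`, `markup` (z-scored), `resampled`, `design`, `bold`,
#'   `truth`. The ground truth's `wordCluster` covers the whole vocabulary;
#'   its `trueWeights` are feature-level (voxels x features).
#' @export
generateSyntheticStudy <- function(cfg = syntheticConfig(), lanczosA = 3) {
  embL <- generateEmbeddings(cfg)
  vocab <- syntheticVocabulary(cfg, embL)
  stream <- generateTokenStream(cfg, embL)
  markup <- zscoreRows(buildMarkupMatrix(stream, embL$emb, vocab))
  resampled <- lanczosResample(markup, tr = cfg@tr, windowA = lanczosA)
  design <- delayEmbed(resampled, cfg@delays)
  featClusters <- unname(embL$clusters[featureWords(vocab)])
  gb <- generateBold(design, cfg, featClusters)
  gb$truth@wordCluster <- embL$clusters
  list(cfg = cfg, emb = embL$emb, clusters = embL$clusters, vocab = vocab,
       stream = stream, markup = markup, resampled = resampled,
       design = design, bold = gb$bold, truth = gb$truth)
}

#' Generate a planted embedding with a designated threat blob
#'
#' Builds word blobs around well-separated centroids, with one designated
#' blob — the "threat" semantics — placed farther from the embedding
#' center than the rest, so it is peripheral in the component space the
#' threat analysis operates on. Vectors are not renormalized: the planted
#' radii are the ground truth the analysis should recover.
#'
#' @param nBlobs number of word blobs (default 5).
#' @param blobSize words per blob (default 20).
#' @param dim embedding dimensionality (default 30).
#' @param threatBlob index of the designated threat blob (default 1).
#' @param threatScale radial scale of the threat blob's centroid relative
#'   to the others (default 2.5).
#' @param spread isotropic within-blob standard deviation (default 0.05).
#' @param seed integer RNG seed.
#' @return list with `emb` (an [EmbeddingTable-class]), `clusters` (named
#'   integer blob per word) and `threatWords` (the threat blob's words).
#' @export
generateThreatEmbeddings <- function(nBlobs = 5, blobSize = 20, dim = 30,
                                     threatBlob = 1, threatScale = 2.5,
                                     spread = 0.05, seed = 1) {
  withSeed(seed, {
    cents <- drawSeparatedCentroids(nBlobs, dim)
    cents[threatBlob, ] <- cents[threatBlob, ] * threatScale
    n <- nBlobs * blobSize
    clusters <- rep(seq_len(nBlobs), each = blobSize)
    v <- cents[clusters, , drop = FALSE] +
      matrix(stats::rnorm(n * dim, sd = spread), n, dim)
    words <- sprintf("blob%d_word%02d", clusters,
                     sequence(rep(blobSize, nBlobs)))
    rownames(v) <- words
    names(clusters) <- words
    list(emb = EmbeddingTable(v), clusters = clusters,
         threatWords = words[clusters == threatBlob])
  })
}
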