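#' @import methods
NULL

## Central containers of the pipeline. All matrices that carry time series are
## stored [series x samples] (features or voxels in rows, TR samples in
## columns); regression maths transposes internally to the conventional
## [samples x predictors] orientation.

#' Timed, lemmatized word tokens of one stimulus run
#'
#' Holds the lemma of every spoken word together with its temporal boundaries
#' (seconds from run onset) and the total run duration. Tokens are kept sorted
#' by onset.
#'
#' @slot tokens data.frame with columns `lemma` (character), `t_start`,
#'   `t_end` (numeric seconds).
#' @slot duration numeric(1), run length in seconds; at least the last
#'   `t_end`.
#' @exportClass TokenStream
setClass("TokenStream",
  representation(tokens = "data.frame", duration = "numeric"))

setValidity("TokenStream", function(object) {
  tk <- object@tokens
  msg <- character()
  need <- c("lemma", "t_start", "t_end")
  if (!all(need %in% names(tk)))
    return(sprintf("tokens must have columns %s", paste(need, collapse = ", ")))
  if (nrow(tk) == 0) msg <- c(msg, "token stream is empty")
  if (any(!nzchar(tk$lemma))) msg <- c(msg, "empty lemma")
  if (any(tk$t_start < 0)) msg <- c(msg, "t_start must be >= 0")
  if (any(tk$t_start >= tk$t_end)) msg <- c(msg, "t_start must be < t_end")
  if (is.unsorted(tk$t_start)) msg <- c(msg, "tokens must be sorted by t_start")
  if (length(object@duration) != 1 || object@duration < max(tk$t_end))
    msg <- c(msg, "duration must be a scalar >= the last t_end")
  if (length(msg)) msg else TRUE
})

#' Word-embedding lookup table
#'
#' A dense matrix of word vectors, one row per word (rownames are the words),
#' as read from word2vec text format.
#'
#' @slot vectors numeric matrix (words x dim) with word rownames.
#' @exportClass EmbeddingTable
setClass("EmbeddingTable", representation(vectors = "matrix"))

setValidity("EmbeddingTable", function(object) {
  v <- object@vectors
  msg <- character()
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "vectors must have unique word rownames")
  if (ncol(v) < 2) msg <- c(msg, "embedding dimensionality must be >= 2")
  if (!all(is.finite(v))) msg <- c(msg, "embedding vectors must be finite")
  if (length(msg)) msg else TRUE
})

#' Ordered feature-word vocabulary (nouns then verbs)
#'
#' @slot nouns character vector, order preserved.
#' @slot verbs character vector, order preserved.
#' @exportClass FeatureVocabulary
setClass("FeatureVocabulary",
  representation(nouns = "character", verbs = "character"))

setValidity("FeatureVocabulary", function(object) {
  all <- c(object@nouns, object@verbs)
  if (length(all) == 0) return("vocabulary is empty")
  if (anyDuplicated(all)) return("duplicated feature words")
  if (any(!nzchar(all))) return("empty feature word")
  TRUE
})

#' Feature-word similarity (markup) matrix on word time stamps
#'
#' One column per token, one row per feature word; entry (i, j) is the cosine
#' similarity between token j's embedding and feature word i's embedding.
#' After row standardization (`standardized = TRUE`) entries are z-scores and
#' no longer bounded by \[-1, 1\].
#'
#' @slot values numeric matrix (features x words).
#' @slot wordTimes numeric, per-column time stamp (token midpoint, seconds).
#' @slot duration numeric(1), run length in seconds.
#' @slot standardized logical(1), whether rows have been z-scored.
#' @exportClass StimulusMatrix
setClass("StimulusMatrix",
  representation(values = "matrix", wordTimes = "numeric",
                 duration = "numeric", standardized = "logical"),
  prototype(standardized = FALSE))

setValidity("StimulusMatrix", function(object) {
  msg <- character()
  if (length(object@wordTimes) != ncol(object@values))
    msg <- c(msg, "wordTimes length must equal number of columns")
  if (is.unsorted(object@wordTimes, strictly = TRUE))
    msg <- c(msg, "wordTimes must be strictly increasing")
  if (is.null(rownames(object@values)))
    msg <- c(msg, "values must carry feature-word rownames")
  if (!all(is.finite(object@values))) msg <- c(msg, "non-finite markup values")
  if (!object@standardized &&
      any(abs(object@values) > 1 + 1e-8))
    msg <- c(msg, "raw similarity entries must lie in [-1, 1]")
  if (length(object@duration) != 1 || object@duration <= 0 ||
      (length(object@wordTimes) && object@duration < max(object@wordTimes)))
    msg <- c(msg, "duration must cover all word times")
  if (length(msg)) msg else TRUE
})

#' Feature series resampled onto the scanner TR grid
#'
#' @slot values numeric matrix (features x samples); column k is the grid
#'   point at time (k - 1) * tr.
#' @slot tr numeric(1), repetition time in seconds.
#' @exportClass ResampledDesign
setClass("ResampledDesign", representation(values = "matrix", tr = "numeric"))

setValidity("ResampledDesign", function(object) {
  if (length(object@tr) != 1 || object@tr <= 0) return("tr must be a positive scalar")
  if (!all(is.finite(object@values))) return("non-finite design values")
  TRUE
})

#' Delay-embedded design matrix
#'
#' Rows are ordered feature-major: all delayed copies of feature 1, then all
#' copies of feature 2, and so on; within a feature the copies follow the
#' order of `delays`.
#'
#' @slot values numeric matrix ((features * delays) x samples).
#' @slot delays numeric, delays in seconds, strictly increasing, >= 0.
#' @slot tr numeric(1), repetition time in seconds.
#' @slot nFeatures integer(1), number of underlying (undelayed) features.
#' @exportClass DelayedDesign
setClass("DelayedDesign",
  representation(values = "matrix", delays = "numeric", tr = "numeric",
                 nFeatures = "integer"))

setValidity("DelayedDesign", function(object) {
  msg <- character()
  if (any(object@delays < 0)) msg <- c(msg, "delays must be >= 0")
  if (is.unsorted(object@delays, strictly = TRUE))
    msg <- c(msg, "delays must be strictly increasing")
  if (nrow(object@values) != object@nFeatures * length(object@delays))
    msg <- c(msg, "row count must be nFeatures * length(delays)")
  if (length(msg)) msg else TRUE
})

#' Sampled haemodynamic response function
#'
#' Standard double-gamma difference, zero at onset, unit peak, with a late
#' undershoot.
#'
#' @slot times numeric sampling grid (seconds from event onset).
#' @slot amplitudes numeric response values on `times`.
#' @slot peakTime numeric(1), time of the global maximum.
#' @exportClass HrfCurve
setClass("HrfCurve",
  representation(times = "numeric", amplitudes = "numeric",
                 peakTime = "numeric"))

setValidity("HrfCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@amplitudes))
    msg <- c(msg, "times and amplitudes must have equal length")
  if (abs(object@amplitudes[1]) > 1e-8) msg <- c(msg, "amplitude at onset must be 0")
  if (sum(object@amplitudes) <= 0) msg <- c(msg, "curve must integrate to a positive value")
  if (length(msg)) msg else TRUE
})

#' Masked voxel time series with coordinates
#'
#' @slot values numeric matrix (voxels x samples).
#' @slot coords integer matrix (voxels x 3) of voxel grid / MNI coordinates,
#'   unique per row, columns x, y, z. Voxels are flattened x-fastest within
#'   the mask (column-major scan order of the volume).
#' @slot tr numeric(1), repetition time in seconds.
#' @exportClass BoldMatrix
setClass("BoldMatrix",
  representation(values = "matrix", coords = "matrix", tr = "numeric"))

setValidity("BoldMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@values))) msg <- c(msg, "non-finite BOLD values")
  if (nrow(object@coords) != nrow(object@values) || ncol(object@coords) != 3)
    msg <- c(msg, "coords must be [voxels x 3]")
  if (anyDuplicated(object@coords)) msg <- c(msg, "voxel coordinates must be unique")
  if (length(object@tr) != 1 || object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (length(msg)) msg else TRUE
})

#' Nested train/validation/test split along the time axis
#'
#' Contiguous-in-time partition: the first `outerTrain` samples train the
#' model, the last `outerTest` verify it; within the training block the first
#' `innerTrain` fit candidate regularizers and the following `innerVal`
#' select among them.
#'
#' @slot outerTrain,outerTest,innerTrain,innerVal integer(1) sample counts.
#' @exportClass SplitScheme
setClass("SplitScheme",
  representation(outerTrain = "integer", outerTest = "integer",
                 innerTrain = "integer", innerVal = "integer"))

setValidity("SplitScheme", function(object) {
  msg <- character()
  v <- c(object@outerTrain, object@outerTest, object@innerTrain, object@innerVal)
  if (any(v <= 0)) msg <- c(msg, "all split sizes must be positive")
  if (object@innerTrain + object@innerVal != object@outerTrain)
    msg <- c(msg, "innerTrain + innerVal must equal outerTrain")
  if (length(msg)) msg else TRUE
})

#' Fitted voxel-wise encoding model
#'
#' @slot weights numeric matrix (voxels x delayed features) of ridge weights.
#' @slot alpha numeric(1), the selected regularization strength.
#' @slot perVoxelR numeric, held-out Pearson correlation per voxel.
#' @slot split the [SplitScheme-class] used.
#' @slot efficiencyCurve data.frame with columns `alpha`, `meanR`: the
#'   cross-validation curve over the candidate grid.
#' @slot delays numeric, the delay-embedding delays (seconds).
#' @slot nFeatures integer(1), number of undelayed features.
#' @slot finalFit character(1), "all" or "train": which samples produced
#'   `weights`.
#' @exportClass EncodingResult
setClass("EncodingResult",
  representation(weights = "matrix", alpha = "numeric", perVoxelR = "numeric",
                 split = "SplitScheme", efficiencyCurve = "data.frame",
                 delays = "numeric", nFeatures = "integer",
                 finalFit = "character"))

setValidity("EncodingResult", function(object) {
  msg <- character()
  if (!all(is.finite(object@weights))) msg <- c(msg, "non-finite weights")
  if (any(abs(object@perVoxelR) > 1 + 1e-12))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(object@alpha) != 1 || object@alpha <= 0)
    msg <- c(msg, "alpha must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Principal-component space of an encoding weight matrix
#'
#' Mean-centered, unscaled PCA. Observations are the rows of the input
#' (voxels); variables are its columns (feature words). Component signs
#' follow the convention that the largest-magnitude loading is positive.
#'
#' @slot scores numeric matrix (observations x components).
#' @slot loadings numeric matrix (variables x components), orthonormal
#'   columns.
#' @slot explainedVariance numeric, fraction of total variance per component.
#' @slot center numeric, the column means removed before projection.
#' @exportClass PcaSpace
setClass("PcaSpace",
  representation(scores = "matrix", loadings = "matrix",
                 explainedVariance = "numeric", center = "numeric"))

setValidity("PcaSpace", function(object) {
  msg <- character()
  k <- ncol(object@loadings)
  if (ncol(object@scores) != k) msg <- c(msg, "scores/loadings component mismatch")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(k))) > 1e-6) msg <- c(msg, "loadings columns must be orthonormal")
  if (is.unsorted(rev(object@explainedVariance)))
    msg <- c(msg, "explainedVariance must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' k-means clustering of feature words in component space
#'
#' @slot labels integer cluster id per point, named by feature word, values
#'   in 1..k.
#' @slot centers numeric matrix (k x components).
#' @slot k integer(1).
#' @slot seed integer(1) RNG seed used for k-means++ initialization.
#' @slot inertia numeric(1), within-cluster sum of squares at convergence.
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(labels = "integer", centers = "matrix", k = "integer",
                 seed = "integer", inertia = "numeric"))

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (any(object@labels < 1L | object@labels > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (nrow(object@centers) != object@k) msg <- c(msg, "centers must have k rows")
  if (object@inertia < 0) msg <- c(msg, "inertia must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Voxel localization of semantic clusters
#'
#' @slot table data.frame with columns `cluster`, `voxel`, `x`, `y`, `z`,
#'   `score`: the highest-scoring voxels of each cluster.
#' @slot topFraction numeric(1), fraction of voxels kept per cluster.
#' @exportClass ClusterLocalization
setClass("ClusterLocalization",
  representation(table = "data.frame", topFraction = "numeric"))

setValidity("ClusterLocalization", function(object) {
  need <- c("cluster", "voxel", "x", "y", "z", "score")
  if (!all(need %in% names(object@table)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (nrow(object@table) && !all(is.finite(object@table$score)))
    return("scores must be finite")
  TRUE
})

#' Individual threat-semantics report
#'
#' @slot table data.frame with columns `cluster`, `medianDistance`, `size`,
#'   `words`, sorted by median distance ascending.
#' @slot nearestCluster integer(1), id of the cluster with the minimal median
#'   distance to the seed words.
#' @slot nearestWords character, member words of that cluster.
#' @slot metadata list: fraction, repeats, seed, k, metric, seed words used.
#' @exportClass ThreatReport
setClass("ThreatReport",
  representation(table = "data.frame", nearestCluster = "integer",
                 nearestWords = "character", metadata = "list"))

setValidity("ThreatReport", function(object) {
  tb <- object@table
  if (any(tb$medianDistance < -1e-12)) return("distances must be >= 0")
  if (is.unsorted(tb$medianDistance)) return("table must be sorted by medianDistance")
  if (abs(min(tb$medianDistance) -
          tb$medianDistance[match(object@nearestCluster, tb$cluster)]) > 1e-12)
    return("nearestCluster must attain the minimal median distance")
  TRUE
})

#' Configuration of the synthetic study generator
#'
#' Defaults mirror the scales of the study the pipeline targets: 300-d
#' embeddings, 997 feature words, TR 1.01 s, delays 2/4/6/8 s, and a run
#' duration of 490 TR samples.
#'
#' @slot nVocabWords,embeddingDim,nPlantedClusters,nFeatureWords,nVoxels
#'   integer(1) counts.
#' @slot runDuration numeric(1) seconds; wordRate numeric(1) words per
#'   second; tr numeric(1) seconds; delays numeric seconds.
#' @slot trueWeightSparsity numeric(1) in \[0, 1\]: fraction of a voxel's
#'   within-cluster features carrying non-zero true weight.
#' @slot noiseSd numeric(1): noise standard deviation relative to each
#'   voxel's signal standard deviation (1 = SNR 1).
#' @slot seed integer(1) master RNG seed.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(nVocabWords = "integer", embeddingDim = "integer",
                 nPlantedClusters = "integer", nFeatureWords = "integer",
                 runDuration = "numeric", wordRate = "numeric",
                 tr = "numeric", delays = "numeric", nVoxels = "integer",
                 trueWeightSparsity = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  cnt <- c(object@nVocabWords, object@embeddingDim, object@nPlantedClusters,
           object@nFeatureWords, object@nVoxels)
  if (any(cnt <= 0)) msg <- c(msg, "all counts must be positive")
  if (object@nPlantedClusters > object@nVocabWords)
    msg <- c(msg, "more planted clusters than vocabulary words")
  if (object@nFeatureWords > object@nVocabWords)
    msg <- c(msg, "more feature words than vocabulary words")
  if (object@trueWeightSparsity < 0 || object@trueWeightSparsity > 1)
    msg <- c(msg, "trueWeightSparsity must lie in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@runDuration <= 0 || object@wordRate <= 0 || object@tr <= 0)
    msg <- c(msg, "runDuration, wordRate and tr must be positive")
  if (length(msg)) msg else TRUE
})

#' Planted ground truth of a synthetic study
#'
#' @slot trueWeights numeric matrix (voxels x features) of planted
#'   feature-level weights.
#' @slot wordCluster named integer, planted cluster of every vocabulary word.
#' @slot voxelCluster integer, planted cluster of every voxel.
#' @slot delayAmplitudes numeric, HRF amplitude applied to each delayed copy.
#' @slot noiseSd numeric(1), realized relative noise level.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(trueWeights = "matrix", wordCluster = "integer",
                 voxelCluster = "integer", delayAmplitudes = "numeric",
                 noiseSd = "numeric"))
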