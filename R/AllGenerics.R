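#' Extract the underlying numeric series matrix
#'
#' Returns the (series x samples) matrix held by a container (features or
#' voxels in rows, time samples in columns).
#'
#' @param x a container object.
#' @return numeric matrix.
#' @export
setGeneric("seriesMatrix", function(x) standardGeneric("seriesMatrix"))

#' @describeIn seriesMatrix markup values (features x words).
setMethod("seriesMatrix", "StimulusMatrix", function(x) x@values)
#' @describeIn seriesMatrix resampled values (features x TR samples).
setMethod("seriesMatrix", "ResampledDesign", function(x) x@values)
#' @describeIn seriesMatrix delayed values (delayed features x TR samples).
setMethod("seriesMatrix", "DelayedDesign", function(x) x@values)
#' @describeIn seriesMatrix voxel values (voxels x TR samples).
setMethod("seriesMatrix", "BoldMatrix", function(x) x@values)

#' Z-score the rows of a matrix-like object
#'
#' Each row is centered and divided by its population standard deviation
#' (divide-by-n convention). Constant rows become all-zero with a warning so
#' downstream regression stays finite.
#'
#' @param x matrix, [StimulusMatrix-class] or [BoldMatrix-class].
#' @return object of the same class with standardized rows.
#' @export
setGeneric("zscoreRows", function(x) standardGeneric("zscoreRows"))

#' Linearly detrend and z-score voxel rows
#'
#' @param x matrix or [BoldMatrix-class]; rows are series over the sample
#'   axis.
#' @return object of the same class; each row has zero best-fit linear
#'   trend, mean 0 and population sd 1.
#' @export
setGeneric("detrendAndZscore", function(x) standardGeneric("detrendAndZscore"))

#' @rdname tokenAccessors
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))
#' @rdname tokenAccessors
#' @export
setGeneric("runDuration", function(x) standardGeneric("runDuration"))

#' Accessors for TokenStream
#'
#' @param x a [TokenStream-class].
#' @return `tokens()` the token data.frame; `runDuration()` the run length
#'   in seconds.
#' @name tokenAccessors
NULL

setMethod("tokens", "TokenStream", function(x) x@tokens)
setMethod("runDuration", "TokenStream", function(x) x@duration)
setMethod("runDuration", "StimulusMatrix", function(x) x@duration)

#' @rdname embeddingAccessors
#' @export
setGeneric("embeddingVectors", function(x) standardGeneric("embeddingVectors"))
#' @rdname embeddingAccessors
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' Accessors for EmbeddingTable
#'
#' @param x an [EmbeddingTable-class].
#' @return `embeddingVectors()` the (words x dim) matrix; `embeddingDim()`
#'   its dimensionality.
#' @name embeddingAccessors
NULL

setMethod("embeddingVectors", "EmbeddingTable", function(x) x@vectors)
setMethod("embeddingDim", "EmbeddingTable", function(x) ncol(x@vectors))

#' Feature words of a vocabulary, nouns first then verbs
#'
#' @param x a [FeatureVocabulary-class].
#' @return character vector.
#' @export
setGeneric("featureWords", function(x) standardGeneric("featureWords"))
setMethod("featureWords", "FeatureVocabulary",
          function(x) c(x@nouns, x@verbs))

#' @rdname designAccessors
#' @export
setGeneric("wordTimes", function(x) standardGeneric("wordTimes"))
#' @rdname designAccessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname designAccessors
#' @export
setGeneric("designDelays", function(x) standardGeneric("designDelays"))

#' Accessors for design-side containers
#'
#' @param x a [StimulusMatrix-class], [ResampledDesign-class],
#'   [DelayedDesign-class] or [BoldMatrix-class].
#' @return `wordTimes()` per-column time stamps; `repetitionTime()` the TR
#'   in seconds; `designDelays()` the delays of a delayed design.
#' @name designAccessors
NULL

setMethod("wordTimes", "StimulusMatrix", function(x) x@wordTimes)
setMethod("repetitionTime", "ResampledDesign", function(x) x@tr)
setMethod("repetitionTime", "DelayedDesign", function(x) x@tr)
setMethod("repetitionTime", "BoldMatrix", function(x) x@tr)
setMethod("designDelays", "DelayedDesign", function(x) x@delays)

#' Voxel coordinates of a BOLD matrix
#'
#' @param x a [BoldMatrix-class].
#' @return integer matrix (voxels x 3).
#' @export
setGeneric("voxelCoords", function(x) standardGeneric("voxelCoords"))
setMethod("voxelCoords", "BoldMatrix", function(x) x@coords)

#' @rdname encodingAccessors
#' @export
setGeneric("encodingWeights", function(x) standardGeneric("encodingWeights"))
#' @rdname encodingAccessors
#' @export
setGeneric("chosenAlpha", function(x) standardGeneric("chosenAlpha"))
#' @rdname encodingAccessors
#' @export
setGeneric("perVoxelR", function(x) standardGeneric("perVoxelR"))
#' @rdname encodingAccessors
#' @export
setGeneric("efficiencyCurve", function(x) standardGeneric("efficiencyCurve"))

#' Accessors for EncodingResult
#'
#' @param x an [EncodingResult-class].
#' @return `encodingWeights()` the (voxels x delayed features) weight
#'   matrix; `chosenAlpha()` the selected regularizer; `perVoxelR()`
#'   held-out correlations; `efficiencyCurve()` the alpha/meanR curve.
#' @name encodingAccessors
NULL

setMethod("encodingWeights", "EncodingResult", function(x) x@weights)
setMethod("chosenAlpha", "EncodingResult", function(x) x@alpha)
setMethod("perVoxelR", "EncodingResult", function(x) x@perVoxelR)
setMethod("efficiencyCurve", "EncodingResult", function(x) x@efficiencyCurve)

#' @rdname pcaAccessors
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))
#' @rdname pcaAccessors
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))
#' @rdname pcaAccessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' Accessors for PcaSpace
#'
#' @param x a [PcaSpace-class].
#' @return `pcaScores()` (observations x components); `pcaLoadings()`
#'   (variables x components); `explainedVariance()` per-component variance
#'   fractions.
#' @name pcaAccessors
NULL

setMethod("pcaScores", "PcaSpace", function(x) x@scores)
setMethod("pcaLoadings", "PcaSpace", function(x) x@loadings)
setMethod("explainedVariance", "PcaSpace", function(x) x@explainedVariance)

#' @rdname clusterAccessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname clusterAccessors
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))
#' @rdname clusterAccessors
#' @export
setGeneric("clusterInertia", function(x) standardGeneric("clusterInertia"))

#' Accessors for ClusterModel
#'
#' @param x a [ClusterModel-class].
#' @return `clusterLabels()` named integer labels; `clusterCenters()` the
#'   (k x components) centers; `clusterInertia()` the within-cluster sum of
#'   squares.
#' @name clusterAccessors
NULL

setMethod("clusterLabels", "ClusterModel", function(x) x@labels)
setMethod("clusterCenters", "ClusterModel", function(x) x@centers)
setMethod("clusterInertia", "ClusterModel", function(x) x@inertia)

#' Localization table of semantic clusters
#'
#' @param x a [ClusterLocalization-class].
#' @return data.frame with columns cluster, voxel, x, y, z, score.
#' @export
setGeneric("localizationTable", function(x) standardGeneric("localizationTable"))
setMethod("localizationTable", "ClusterLocalization", function(x) x@table)

#' @rdname threatAccessors
#' @export
setGeneric("threatTable", function(x) standardGeneric("threatTable"))
#' @rdname threatAccessors
#' @export
setGeneric("nearestThreatCluster", function(x) standardGeneric("nearestThreatCluster"))

#' Accessors for ThreatReport
#'
#' @param x a [ThreatReport-class].
#' @return `threatTable()` the per-cluster median-distance table;
#'   `nearestThreatCluster()` a list with the nearest cluster id and its
#'   member words.
#' @name threatAccessors
NULL

setMethod("threatTable", "ThreatReport", function(x) x@table)
setMethod("nearestThreatCluster", "ThreatReport",
          function(x) list(cluster = x@nearestCluster, words = x@nearestWords))
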