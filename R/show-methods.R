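## Compact show() methods for the central containers.

setMethod("show", "TokenStream", function(object) {
  tk <- object@tokens
  cat("TokenStream with", nrow(tk), "tokens over",
      sprintf("%.1f s", object@duration), "\n")
  cat("  first:", paste(utils::head(tk$lemma, 5), collapse = " "), "...\n")
})

setMethod("show", "EmbeddingTable", function(object) {
  cat("EmbeddingTable:", nrow(object@vectors), "words x",
      ncol(object@vectors), "dimensions\n")
})

setMethod("show", "FeatureVocabulary", function(object) {
  cat("FeatureVocabulary:", length(object@nouns), "nouns +",
      length(object@verbs), "verbs =",
      length(object@nouns) + length(object@verbs), "feature words\n")
})

setMethod("show", "StimulusMatrix", function(object) {
  cat("StimulusMatrix:", nrow(object@values), "features x",
      ncol(object@values), "words",
      if (object@standardized) "(row z-scored)" else "(raw similarities)",
      "\n")
})

setMethod("show", "ResampledDesign", function(object) {
  cat("ResampledDesign:", nrow(object@values), "features x",
      ncol(object@values), "TR samples (tr =", object@tr, "s)\n")
})

setMethod("show", "DelayedDesign", function(object) {
  cat("DelayedDesign:", nrow(object@values), "delayed features (",
      object@nFeatures, "x", length(object@delays), "delays:",
      paste(object@delays, collapse = ", "), "s ) x", ncol(object@values),
      "samples\n")
})

setMethod("show", "BoldMatrix", function(object) {
  cat("BoldMatrix:", nrow(object@values), "voxels x", ncol(object@values),
      "samples (tr =", object@tr, "s)\n")
})

setMethod("show", "SplitScheme", function(object) {
  cat("SplitScheme: outer", object@outerTrain, "/", object@outerTest,
      ", inner", object@innerTrain, "/", object@innerVal, "\n")
})

setMethod("show", "EncodingResult", function(object) {
  cat("EncodingResult:", nrow(object@weights), "voxels x",
      ncol(object@weights), "delayed features\n")
  cat(sprintf("  alpha = %.4f (fit on %s samples); held-out r: mean %.4f, max %.4f\n",
              object@alpha, object@finalFit, mean(object@perVoxelR),
              max(object@perVoxelR)))
})

setMethod("show", "PcaSpace", function(object) {
  cat("PcaSpace:", nrow(object@scores), "observations,",
      nrow(object@loadings), "variables,", ncol(object@loadings),
      "components\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * object@explainedVariance),
            collapse = " "), "\n")
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: k =", object@k, "over", length(object@labels),
      "points; inertia =", signif(object@inertia, 6), "\n")
})

setMethod("show", "ClusterLocalization", function(object) {
  cat("ClusterLocalization:", nrow(object@table), "voxel entries over",
      length(unique(object@table$cluster)), "clusters (top",
      sprintf("%.1f%%", 100 * object@topFraction), "per cluster)\n")
})

setMethod("show", "ThreatReport", function(object) {
  cat("ThreatReport: nearest cluster", object@nearestCluster,
      sprintf("(median distance %.4f)\n", object@table$medianDistance[1]))
  cat("  members:", paste(utils::head(object@nearestWords, 8),
                          collapse = " "),
      if (length(object@nearestWords) > 8) "...\n" else "\n")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nVocabWords, "words,",
      object@nFeatureWords, "features,", object@nPlantedClusters,
      "planted clusters,", object@nVoxels, "voxels\n")
  cat(sprintf("  run %.1f s @ %.2f words/s, tr %.2f s, noise sd %.2f x signal, seed %d\n",
              object@runDuration, object@wordRate, object@tr,
              object@noiseSd, object@seed))
})
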