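## Pipeline driver: one configured call from input files to the full set
## of result artifacts.

#' Build and validate a pipeline configuration
#'
#' Collects every path and tunable of the full analysis. The resolved
#' configuration is serialized (JSON) next to the outputs of each run and
#' its checksum is echoed into every result file.
#'
#' @param annotationFile,embeddingFile,nounsFile,verbsFile,boldFile,maskFile
#'   input paths (see the readers in this package).
#' @param outDir output directory.
#' @param tr repetition time in seconds (default 1.01).
#' @param delays haemodynamic delays in seconds (default 2, 4, 6, 8).
#' @param lanczosA Lanczos window parameter (default 3).
#' @param alphas regularizer candidate grid (default [defaultAlphaGrid()]).
#' @param split optional [SplitScheme-class]; default scales 350/140 +
#'   300/50 to the run length.
#' @param probeVoxels probe voxels for the alpha search (default 500).
#' @param topVoxels number of best-predicted voxels kept for clustering
#'   (default 10000, capped at the voxel count).
#' @param nComponents PCA components (default 4).
#' @param kSemantic semantic cluster count (default 15).
#' @param kThreat threat-analysis cluster count (default 12).
#' @param fraction peripheral-selection fraction (default 0.8).
#' @param repeats peripheral-selection repeats (default 100).
#' @param localizeFraction voxel fraction kept per localized cluster
#'   (default 0.05).
#' @param threatSeeds optional character vector of threat seed words; the
#'   threat stage runs only when provided.
#' @param oov out-of-vocabulary policy, `"error"` or `"skip"`.
#' @param finalFit `"all"` or `"train"` (see [fitEncodingModel()]).
#' @param seed master RNG seed.
#' @param saveWeights also write the full delayed-weight matrix (large);
#'   default `FALSE` writes the delay-averaged weights only.
#' @return validated configuration list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(annotationFile, embeddingFile, nounsFile,
                           verbsFile, boldFile, maskFile, outDir,
                           tr = 1.01, delays = c(2, 4, 6, 8), lanczosA = 3,
                           alphas = defaultAlphaGrid(), split = NULL,
                           probeVoxels = 500, topVoxels = 10000,
                           nComponents = 4, kSemantic = 15, kThreat = 12,
                           fraction = 0.8, repeats = 100,
                           localizeFraction = 0.05, threatSeeds = NULL,
                           oov = c("error", "skip"),
                           finalFit = c("all", "train"), seed = 1,
                           saveWeights = FALSE) {
  cfg <- list(annotationFile = annotationFile, embeddingFile = embeddingFile,
              nounsFile = nounsFile, verbsFile = verbsFile,
              boldFile = boldFile, maskFile = maskFile, outDir = outDir,
              tr = tr, delays = delays, lanczosA = lanczosA,
              alphas = alphas, split = split, probeVoxels = probeVoxels,
              topVoxels = topVoxels, nComponents = nComponents,
              kSemantic = kSemantic, kThreat = kThreat,
              fraction = fraction, repeats = repeats,
              localizeFraction = localizeFraction,
              threatSeeds = threatSeeds, oov = match.arg(oov),
              finalFit = match.arg(finalFit), seed = seed,
              saveWeights = saveWeights)
  for (f in c("annotationFile", "embeddingFile", "nounsFile", "verbsFile",
              "boldFile", "maskFile")) {
    if (!file.exists(cfg[[f]])) stop(f, " does not exist: ", cfg[[f]])
  }
  if (tr <= 0) stop("tr must be positive")
  if (!is.null(split) && split@innerTrain + split@innerVal != split@outerTrain)
    stop("invalid split: innerTrain + innerVal must equal outerTrain")
  class(cfg) <- "pipelineConfig"
  cfg
}

# TSV writer that stamps the config checksum as a comment first line.
writeStamped <- function(df, path, stamp) {
  writeLines(paste0("# config_md5 ", stamp), path)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  path
}

#' Run the full semantic-mapping pipeline
#'
#' Executes markup construction, TR-grid resampling, delay embedding,
#' encoding-model fitting with alpha selection, delay averaging, voxel
#' selection, PCA, semantic k-means clustering, voxel localization, and
#' (when seed words are configured) the threat report. All stages are
#' deterministic given the configured seed; rerunning on identical inputs
#' produces byte-identical output files.
#'
#' @param cfg a configuration from [pipelineConfig()].
#' @return invisibly, a list with the in-memory results (`markup`,
#'   `design`, `bold`, `encoding`, `weightsAvg`, `topVoxels`, `space`,
#'   `clusters`, `localization`, `threat`) and `files`, the paths written.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$outDir, f)

  emb <- stage("read", readWordEmbeddings(cfg$embeddingFile))
  vocab <- stage("read", readFeatureVocabulary(cfg$nounsFile, cfg$verbsFile))
  stream <- stage("read", readWordAnnotations(cfg$annotationFile))
  bold <- stage("read", readBoldNifti(cfg$boldFile, cfg$maskFile, cfg$tr))

  markup <- stage("markup",
                  zscoreRows(buildMarkupMatrix(stream, emb, vocab,
                                               oov = cfg$oov)))
  design <- stage("align", {
    rs <- lanczosResample(markup, tr = cfg$tr, windowA = cfg$lanczosA)
    nS <- ncol(seriesMatrix(rs))
    nB <- ncol(seriesMatrix(bold))
    if (nS != nB) {
      n <- min(nS, nB)
      rs@values <- rs@values[, seq_len(n), drop = FALSE]
      bold@values <- bold@values[, seq_len(n), drop = FALSE]
    }
    delayEmbed(rs, cfg$delays)
  })
  bold <- stage("fit", detrendAndZscore(bold))
  split <- if (is.null(cfg$split)) defaultSplit(ncol(seriesMatrix(bold)))
           else cfg$split
  enc <- stage("fit", fitEncodingModel(design, bold, alphas = cfg$alphas,
                                       split = split,
                                       probeVoxels = cfg$probeVoxels,
                                       seed = cfg$seed,
                                       finalFit = cfg$finalFit))
  wAvg <- stage("cluster", averageDelays(enc))
  top <- stage("cluster",
               selectTopVoxels(perVoxelR(enc),
                               min(cfg$topVoxels, length(perVoxelR(enc)))))
  space <- stage("cluster", pcaFit(wAvg[top, , drop = FALSE],
                                   nComponents = cfg$nComponents))
  clusters <- stage("cluster", kmeansFeatures(space, k = cfg$kSemantic,
                                              seed = cfg$seed))
  loc <- stage("cluster",
               localizeClusters(wAvg[top, , drop = FALSE], clusters,
                                voxelCoords(bold)[top, , drop = FALSE],
                                topFraction = cfg$localizeFraction))
  threat <- NULL
  if (!is.null(cfg$threatSeeds)) {
    threat <- stage("threat",
                    threatReport(space, words = featureWords(vocab),
                                 seeds = cfg$threatSeeds, emb = emb,
                                 k = cfg$kThreat, fraction = cfg$fraction,
                                 repeats = cfg$repeats, seed = cfg$seed,
                                 which = "loadings"))
  }

  # serialize: config echo first, its checksum stamped into every table
  cfgEcho <- cfg
  cfgEcho$split <- list(outerTrain = split@outerTrain,
                        outerTest = split@outerTest,
                        innerTrain = split@innerTrain,
                        innerVal = split@innerVal)
  jsonlite::write_json(unclass(cfgEcho), p("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  # the stamp covers the analysis configuration, not the output location
  hashSrc <- cfgEcho
  hashSrc$outDir <- NULL
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(hashSrc), tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  stamp <- unname(tools::md5sum(tmp))
  unlink(tmp)
  files <- c(config = p("config.json"))
  files["summary"] <- p("summary.json")
  jsonlite::write_json(list(config_md5 = stamp, alpha = chosenAlpha(enc),
                            meanHeldOutR = mean(perVoxelR(enc)),
                            nVoxels = nrow(seriesMatrix(bold)),
                            nSamples = ncol(seriesMatrix(bold)),
                            nFeatures = enc@nFeatures,
                            nDelayedFeatures = ncol(encodingWeights(enc))),
                       p("summary.json"), auto_unbox = TRUE, digits = NA)
  files["efficiency"] <- writeStamped(efficiencyCurve(enc),
                                      p("alpha_efficiency.tsv"), stamp)
  co <- voxelCoords(bold)
  files["correlations"] <- writeStamped(
    data.frame(voxel = seq_along(perVoxelR(enc)), x = co[, 1], y = co[, 2],
               z = co[, 3], r = perVoxelR(enc)),
    p("voxel_correlations.tsv"), stamp)
  files["weightsAvg"] <- writeStamped(
    data.frame(voxel = seq_len(nrow(wAvg)),
               round(wAvg, 8), check.names = FALSE),
    p("weights_avg.tsv"), stamp)
  if (isTRUE(cfg$saveWeights)) {
    files["weights"] <- writeStamped(
      data.frame(voxel = seq_len(nrow(encodingWeights(enc))),
                 round(encodingWeights(enc), 8), check.names = FALSE),
      p("weights_delayed.tsv"), stamp)
  }
  lab <- clusterLabels(clusters)
  files["clusterReport"] <- writeStamped(
    data.frame(cluster = sort(unique(lab)),
               size = as.integer(table(lab)),
               words = vapply(sort(unique(lab)), function(cl) {
                 paste(names(lab)[lab == cl], collapse = " ")
               }, character(1))),
    p("cluster_report.tsv"), stamp)
  files["localization"] <- writeStamped(localizationTable(loc),
                                        p("cluster_localization.tsv"), stamp)
  if (!is.null(threat)) {
    files["threat"] <- writeStamped(threatTable(threat),
                                    p("threat_report.tsv"), stamp)
    files["threatSummary"] <- p("threat_summary.json")
    jsonlite::write_json(list(config_md5 = stamp,
                              nearestCluster = threat@nearestCluster,
                              medianDistance = threatTable(threat)$medianDistance[1],
                              words = threat@nearestWords),
                         p("threat_summary.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(markup = markup, design = design, bold = bold,
                 encoding = enc, weightsAvg = wAvg, topVoxels = top,
                 space = space, clusters = clusters, localization = loc,
                 threat = threat, split = split, files = files))
}
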