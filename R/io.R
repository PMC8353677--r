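## Readers and writers for the standard input formats: annotation TSV,
## word2vec text embeddings, vocabulary files, and NIfTI BOLD + mask.

# Parse "MM:SS.s" or plain seconds into float seconds.
parseTimeStamp <- function(x) {
  x <- trimws(as.character(x))
  mmss <- grepl("^\\d+:\\d+(\\.\\d+)?$", x)
  out <- suppressWarnings(as.numeric(x))
  if (any(mmss)) {
    parts <- strsplit(x[mmss], ":", fixed = TRUE)
    out[mmss] <- vapply(parts, function(p) {
      60 * as.numeric(p[1]) + as.numeric(p[2])
    }, numeric(1))
  }
  if (anyNA(out)) stop("unparseable time stamp(s): ",
                       paste(utils::head(x[is.na(out)], 3), collapse = ", "))
  out
}

#' Read a timed word annotation table
#'
#' Tab-separated table with a header row and columns lemma / start / end
#' (matched case-insensitively, otherwise the first three columns are
#' used). Times may be plain seconds or the "MM:SS.s" dialect; both are
#' auto-detected.
#'
#' @param path file path.
#' @param duration optional run length in seconds (defaults to the last
#'   word's end time).
#' @return a [TokenStream-class].
#' @export
readWordAnnotations <- function(path, duration = NULL) {
  tb <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  pick <- function(re) grep(re, names(tb), ignore.case = TRUE)[1]
  iL <- pick("lemma|word")
  iS <- pick("start")
  iE <- pick("end")
  if (anyNA(c(iL, iS, iE))) { iL <- 1; iS <- 2; iE <- 3 }
  ts <- parseTimeStamp(tb[[iS]])
  te <- parseTimeStamp(tb[[iE]])
  TokenStream(tb[[iL]], ts, te,
              duration = if (is.null(duration)) max(te) else duration)
}

#' Write a timed word annotation table
#'
#' @param stream a [TokenStream-class].
#' @param path output path (TSV with columns lemma, start, end in
#'   seconds).
#' @export
writeWordAnnotations <- function(stream, path) {
  tk <- tokens(stream)
  data.table::fwrite(data.frame(lemma = tk$lemma, start = tk$t_start,
                                end = tk$t_end),
                     path, sep = "\t")
  invisible(path)
}

#' Read a word2vec text-format embedding table
#'
#' First line "count dim", then one word and `dim` floats per line.
#' POS-suffixed tokens (e.g. "мир_NOUN") are passed through verbatim.
#'
#' @param path file path.
#' @return an [EmbeddingTable-class].
#' @export
readWordEmbeddings <- function(path) {
  hdr <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  if (length(hdr) != 2) stop("expected 'count dim' header line")
  n <- as.integer(hdr[1]); dim <- as.integer(hdr[2])
  tb <- data.table::fread(path, skip = 1, header = FALSE, sep = " ",
                          data.table = FALSE)
  if (ncol(tb) != dim + 1)
    stop("embedding rows have ", ncol(tb) - 1, " values, header says ", dim)
  if (nrow(tb) != n)
    warning("header declares ", n, " words but file has ", nrow(tb))
  v <- as.matrix(tb[, -1, drop = FALSE])
  dimnames(v) <- list(tb[[1]], NULL)
  EmbeddingTable(v)
}

#' Write a word2vec text-format embedding table
#'
#' @param emb an [EmbeddingTable-class].
#' @param path output path.
#' @export
writeWordEmbeddings <- function(emb, path) {
  v <- embeddingVectors(emb)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(v), ncol(v)), con)
  body <- paste(rownames(v),
                apply(v, 1, function(r) paste(formatC(r, format = "g",
                                                      digits = 8),
                                              collapse = " ")))
  writeLines(body, con)
  invisible(path)
}

#' Read a feature vocabulary from noun and verb word lists
#'
#' One word per line, order preserved.
#'
#' @param nounsPath,verbsPath file paths.
#' @return a [FeatureVocabulary-class].
#' @export
readFeatureVocabulary <- function(nounsPath, verbsPath) {
  rd <- function(p) {
    w <- readLines(p, encoding = "UTF-8", warn = FALSE)
    w[nzchar(trimws(w))]
  }
  FeatureVocabulary(nouns = rd(nounsPath), verbs = rd(verbsPath))
}

#' Write a feature vocabulary to noun and verb word lists
#'
#' @param vocab a [FeatureVocabulary-class].
#' @param nounsPath,verbsPath output paths.
#' @export
writeFeatureVocabulary <- function(vocab, nounsPath, verbsPath) {
  writeLines(vocab@nouns, nounsPath, useBytes = TRUE)
  writeLines(vocab@verbs, verbsPath, useBytes = TRUE)
  invisible(c(nounsPath, verbsPath))
}

#' Read masked BOLD time series from NIfTI files
#'
#' Voxels inside the mask are flattened x-fastest (column-major scan order
#' of the volume), with the grid coordinates of every kept voxel recorded
#' alongside; this order is part of the file contract.
#'
#' @param boldPath 4-D NIfTI of the run.
#' @param maskPath 3-D binary mask NIfTI on the same grid.
#' @param tr repetition time in seconds.
#' @return a [BoldMatrix-class].
#' @export
readBoldNifti <- function(boldPath, maskPath, tr) {
  vol <- RNifti::readNifti(boldPath)
  msk <- RNifti::readNifti(maskPath)
  dv <- dim(vol)
  if (length(dv) != 4) stop("BOLD image must be 4-D")
  if (!all(dim(msk)[1:3] == dv[1:3])) stop("mask grid does not match BOLD")
  keep <- which(msk > 0)
  if (length(keep) == 0) stop("empty mask")
  flat <- matrix(as.numeric(vol), prod(dv[1:3]), dv[4])
  BoldMatrix(flat[keep, , drop = FALSE], arrayInd(keep, dv[1:3]), tr)
}

#' Write masked BOLD time series as NIfTI
#'
#' Inverse of [readBoldNifti()]: voxels are scattered back to their grid
#' coordinates; everything outside the mask is zero.
#'
#' @param bold a [BoldMatrix-class].
#' @param boldPath,maskPath output paths (".nii" or ".nii.gz").
#' @param dims optional 3-D grid dimensions (default: the coordinate
#'   maxima).
#' @export
writeBoldNifti <- function(bold, boldPath, maskPath, dims = NULL) {
  co <- voxelCoords(bold)
  if (is.null(dims)) dims <- apply(co, 2, max)
  v <- seriesMatrix(bold)
  lin <- co[, 1] + (co[, 2] - 1L) * dims[1] + (co[, 3] - 1L) * dims[1] * dims[2]
  vol <- array(0, c(dims, ncol(v)))
  flat <- matrix(0, prod(dims), ncol(v))
  flat[lin, ] <- v
  vol[] <- flat
  msk <- array(0L, dims)
  msk[lin] <- 1L
  RNifti::writeNifti(RNifti::asNifti(vol), boldPath)
  RNifti::writeNifti(RNifti::asNifti(msk), maskPath)
  invisible(c(boldPath, maskPath))
}

#' Write a complete synthetic study to standard input files
#'
#' Emits the four pipeline inputs (annotation TSV, word2vec text
#' embeddings, noun/verb vocabulary lists, BOLD + mask NIfTI) plus the
#' planted ground truth (TSV) and the generator configuration (JSON).
#'
#' @param cfg a [SyntheticConfig-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly; the
#'   generated study list is attached as attribute `"study"`.
#' @export
writeSyntheticStudy <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- generateSyntheticStudy(cfg)
  p <- function(f) file.path(dir, f)
  writeWordAnnotations(st$stream, p("annotations.tsv"))
  writeWordEmbeddings(st$emb, p("embeddings.txt"))
  writeFeatureVocabulary(st$vocab, p("nouns.txt"), p("verbs.txt"))
  writeBoldNifti(st$bold, p("bold.nii.gz"), p("mask.nii.gz"))
  truth <- data.frame(word = names(st$clusters),
                      cluster = as.integer(st$clusters))
  data.table::fwrite(truth, p("planted_word_clusters.tsv"), sep = "\t")
  data.table::fwrite(data.frame(voxel = seq_along(st$truth@voxelCluster),
                                cluster = st$truth@voxelCluster),
                     p("planted_voxel_clusters.tsv"), sep = "\t")
  jsonlite::write_json(
    list(nVocabWords = cfg@nVocabWords, embeddingDim = cfg@embeddingDim,
         nPlantedClusters = cfg@nPlantedClusters,
         nFeatureWords = cfg@nFeatureWords, runDuration = cfg@runDuration,
         wordRate = cfg@wordRate, tr = cfg@tr, delays = cfg@delays,
         nVoxels = cfg@nVoxels, trueWeightSparsity = cfg@trueWeightSparsity,
         noiseSd = cfg@noiseSd, seed = cfg@seed),
    p("synthetic_config.json"), auto_unbox = TRUE, digits = NA)
  files <- c(annotations = p("annotations.tsv"),
             embeddings = p("embeddings.txt"),
             nouns = p("nouns.txt"), verbs = p("verbs.txt"),
             bold = p("bold.nii.gz"), mask = p("mask.nii.gz"),
             wordClusters = p("planted_word_clusters.tsv"),
             voxelClusters = p("planted_voxel_clusters.tsv"),
             config = p("synthetic_config.json"))
  attr(files, "study") <- st
  invisible(files)
}
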