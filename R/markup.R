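## Stimulus markup: timed lemmas + embedding table -> feature-word
## similarity matrix.

#' Construct a TokenStream
#'
#' @param lemma character lemmas.
#' @param t_start,t_end numeric word boundaries in seconds from run onset.
#' @param duration run length in seconds; defaults to the last `t_end`.
#' @return a [TokenStream-class].
#' @export
TokenStream <- function(lemma, t_start, t_end, duration = max(t_end)) {
  tk <- data.frame(lemma = as.character(lemma),
                   t_start = as.numeric(t_start),
                   t_end = as.numeric(t_end))
  tk <- tk[order(tk$t_start), , drop = FALSE]
  rownames(tk) <- NULL
  new("TokenStream", tokens = tk, duration = as.numeric(duration))
}

#' Construct an EmbeddingTable
#'
#' @param vectors numeric matrix (words x dim) with word rownames.
#' @return an [EmbeddingTable-class].
#' @export
EmbeddingTable <- function(vectors) {
  new("EmbeddingTable", vectors = as.matrix(vectors))
}

#' Construct a FeatureVocabulary
#'
#' @param nouns,verbs character vectors of feature words, order preserved;
#'   the combined vocabulary is `c(nouns, verbs)`.
#' @return a [FeatureVocabulary-class].
#' @export
FeatureVocabulary <- function(nouns, verbs = character()) {
  new("FeatureVocabulary", nouns = as.character(nouns),
      verbs = as.character(verbs))
}

# Resolve words in the embedding table, honoring the OOV policy.
lookupEmbeddings <- function(words, emb, oov = c("error", "skip")) {
  oov <- match.arg(oov)
  v <- embeddingVectors(emb)
  idx <- match(words, rownames(v))
  if (anyNA(idx)) {
    missing <- unique(words[is.na(idx)])
    if (oov == "error") {
      stop("out-of-vocabulary word(s): ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
    }
    message("skipping ", length(missing), " out-of-vocabulary word(s)")
  }
  idx
}

#' Build the feature-word markup matrix for a token stream
#'
#' Column j holds the cosine similarities between token j's embedding and
#' every feature word's embedding; columns are time-stamped at the token
#' midpoint `(t_start + t_end) / 2`. A token whose lemma is itself a feature
#' word therefore produces an exact 1 in that feature's row.
#'
#' @param stream a [TokenStream-class].
#' @param emb an [EmbeddingTable-class] resolving every lemma and feature
#'   word.
#' @param vocab a [FeatureVocabulary-class].
#' @param oov what to do with lemmas absent from `emb`: `"error"` (default)
#'   or `"skip"` (drop the token with a message). Feature words must always
#'   resolve.
#' @return a [StimulusMatrix-class] (features x tokens).
#' @export
buildMarkupMatrix <- function(stream, emb, vocab, oov = c("error", "skip")) {
  oov <- match.arg(oov)
  tk <- tokens(stream)
  feats <- featureWords(vocab)
  fIdx <- lookupEmbeddings(feats, emb, oov = "error")
  tIdx <- lookupEmbeddings(tk$lemma, emb, oov = oov)
  keep <- !is.na(tIdx)
  tk <- tk[keep, , drop = FALSE]
  tIdx <- tIdx[keep]
  if (nrow(tk) == 0) stop("no resolvable tokens in stream")
  v <- embeddingVectors(emb)
  fu <- unitRows(v[fIdx, , drop = FALSE], "feature-word embedding")
  tu <- unitRows(v[tIdx, , drop = FALSE], "token embedding")
  vals <- fu %*% t(tu)
  vals[vals > 1] <- 1
  vals[vals < -1] <- -1
  rownames(vals) <- feats
  mid <- (tk$t_start + tk$t_end) / 2
  colnames(vals) <- tk$lemma
  new("StimulusMatrix", values = vals, wordTimes = mid,
      duration = runDuration(stream), standardized = FALSE)
}

# Core row z-scoring with the population-sd convention; constant rows map
# to zeros.
zscoreRowsMatrix <- function(m) {
  mu <- rowMeans(m)
  s <- rowPopSd(m)
  # rows constant up to numerical noise count as constant
  zero <- s <= 1e-10 * pmax(sqrt(rowMeans(m^2)), 1)
  if (any(zero)) {
    warning(sum(zero), " constant row(s) z-scored to zeros")
    s[zero] <- 1
  }
  z <- (m - mu) / s
  z[zero, ] <- 0
  z
}

#' @describeIn zscoreRows plain matrix method.
setMethod("zscoreRows", "matrix", function(x) {
  if (ncol(x) < 2) stop("rows need at least 2 entries to z-score")
  zscoreRowsMatrix(x)
})

#' @describeIn zscoreRows returns a standardized [StimulusMatrix-class].
setMethod("zscoreRows", "StimulusMatrix", function(x) {
  initialize(x, values = zscoreRowsMatrix(x@values), standardized = TRUE)
})
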