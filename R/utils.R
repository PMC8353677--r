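## Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# stream.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Population (divide-by-n) standard deviation per row.
rowPopSd <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowMeans((m - mu)^2))
}

# Row-wise Pearson correlation between two [series x samples] matrices.
# Constant rows yield 0 with a warning (correlation undefined).
rowPearson <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  if (ncol(a) < 3) stop("need at least 3 samples to correlate")
  ca <- a - rowMeans(a)
  cb <- b - rowMeans(b)
  num <- rowSums(ca * cb)
  den <- sqrt(rowSums(ca^2) * rowSums(cb^2))
  bad <- den <= 0
  if (any(bad)) {
    warning(sum(bad), " constant series; correlation set to 0")
    den[bad] <- 1
    num[bad] <- 0
  }
  pmin(1, pmax(-1, num / den))
}

# Unit-normalize matrix rows; errors on zero-norm rows (degenerate
# embeddings).
unitRows <- function(m, what = "vector") {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) stop("zero-norm ", what)
  m / n
}

# Squared Euclidean distances between rows of `x` [n x d] and rows of
# `centers` [k x d].
sqDistToCenters <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

#' Cosine similarity between two vectors
#'
#' @param u,v numeric vectors of equal length with nonzero norm.
#' @return `u . v / (|u| |v|)`, a value in \[-1, 1\].
#' @examples
#' cosineSimilarity(c(1, 2, 2), c(2, 1, 2))  # 8/9
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-norm vector: degenerate embedding")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}
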