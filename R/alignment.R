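## Temporal alignment: Lanczos resampling onto the TR grid and delay
## embedding approximating the haemodynamic response.

# Lanczos kernel in seconds for cutoff frequency fc (Hz) and window a:
# L(t) = sinc(2 fc t) sinc(2 fc t / a) on |2 fc t| < a, else 0.
lanczosKernel <- function(t, fc, a) {
  x <- 2 * fc * t
  out <- numeric(length(x))
  inside <- abs(x) < a & x != 0
  xi <- x[inside]
  out[inside] <- (a * sin(pi * xi) * sin(pi * xi / a)) / (pi^2 * xi^2)
  out[x == 0] <- 1
  out
}

#' Resample a word-timed markup matrix onto the scanner TR grid
#'
#' Each feature's irregular word-time series is interpolated onto the grid
#' `t_k = (k - 1) * tr`, `k = 1 .. ceiling(duration / tr)`, with a windowed-
#' sinc (Lanczos) kernel whose cutoff is the Nyquist frequency of the fMRI
#' acquisition, `1 / (2 tr)`. Kernel weights are normalized per grid point,
#' so a constant series resamples to the same constant and the operation is
#' linear in the feature series.
#'
#' @param sm a [StimulusMatrix-class] (raw or z-scored).
#' @param tr repetition time in seconds.
#' @param windowA Lanczos window parameter `a` (number of side lobes);
#'   default 3.
#' @return a [ResampledDesign-class] (features x samples).
#' @export
lanczosResample <- function(sm, tr, windowA = 3) {
  if (tr <= 0) stop("tr must be positive")
  if (windowA < 1) stop("windowA must be >= 1")
  tau <- wordTimes(sm)
  if (length(tau) == 0) stop("empty token stream")
  dur <- runDuration(sm)
  if (dur < tr) stop("run duration shorter than one TR")
  nOut <- ceiling(dur / tr)
  grid <- (seq_len(nOut) - 1) * tr
  fc <- 1 / (2 * tr)
  # weight matrix [grid x words]; kernel support is |dt| < windowA * tr
  dt <- outer(grid, tau, "-")
  w <- lanczosKernel(dt, fc, windowA)
  dim(w) <- dim(dt)
  rs <- rowSums(w)
  dead <- abs(rs) < 1e-12
  rs[dead] <- 1
  w <- w / rs
  w[dead, ] <- 0
  vals <- seriesMatrix(sm) %*% t(w)
  rownames(vals) <- rownames(seriesMatrix(sm))
  colnames(vals) <- NULL
  new("ResampledDesign", values = vals, tr = tr)
}

#' Delay-embed a resampled design
#'
#' For every delay `d` a shifted copy of each feature series is created:
#' the copy's value at sample `t` is the feature's value at `t - d`
#' (zero-filled before run onset). Delays are converted to integer sample
#' shifts by rounding `delay / tr`; a delay further than 0.15 samples from
#' an integer shift is rejected. Rows are ordered feature-major: all copies
#' of feature 1 (in delay order), then feature 2, and so on.
#'
#' @param rd a [ResampledDesign-class].
#' @param delays numeric delays in seconds, non-negative, strictly
#'   increasing.
#' @return a [DelayedDesign-class] with `nFeatures * length(delays)` rows.
#' @export
delayEmbed <- function(rd, delays) {
  if (any(delays < 0)) stop("delays must be >= 0")
  if (is.unsorted(delays, strictly = TRUE))
    stop("delays must be strictly increasing")
  tr <- repetitionTime(rd)
  shifts <- round(delays / tr)
  off <- abs(delays / tr - shifts)
  if (any(off > 0.15))
    stop("delay(s) ", paste(delays[off > 0.15], collapse = ", "),
         " not representable on the TR grid (tr = ", tr, ")")
  v <- seriesMatrix(rd)
  nf <- nrow(v); nt <- ncol(v); nd <- length(delays)
  if (any(shifts > nt)) stop("delay exceeds run length")
  out <- matrix(0, nf * nd, nt)
  for (d in seq_len(nd)) {
    s <- shifts[d]
    rows <- (seq_len(nf) - 1L) * nd + d
    if (s == 0) {
      out[rows, ] <- v
    } else {
      out[rows, (s + 1):nt] <- v[, seq_len(nt - s), drop = FALSE]
    }
  }
  base <- rownames(v)
  if (!is.null(base)) {
    rownames(out) <- paste0(rep(base, each = nd), "@",
                            rep(delays, times = nf), "s")
  }
  new("DelayedDesign", values = out, delays = as.numeric(delays), tr = tr,
      nFeatures = as.integer(nf))
}

#' Canonical double-gamma haemodynamic response function
#'
#' The standard difference of two gamma densities (response peak near 5 s,
#' undershoot near 15 s, peak-to-undershoot ratio 6), sampled on a regular
#' grid and normalized to unit peak. Used by the synthetic-data generator
#' to shape BOLD responses.
#'
#' @param tr sampling interval in seconds.
#' @param length curve length in seconds (>= 20).
#' @return an [HrfCurve-class].
#' @export
canonicalHrf <- function(tr, length = 32) {
  if (tr <= 0) stop("tr must be positive")
  if (length < 20) stop("length must be >= 20 s")
  t <- seq(0, length, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h <- h / max(h)
  new("HrfCurve", times = t, amplitudes = h, peakTime = t[which.max(h)])
}

#' Evaluate an HRF curve at arbitrary times
#'
#' Linear interpolation on the sampled curve; zero outside its support.
#'
#' @param hrf an [HrfCurve-class].
#' @param t numeric times in seconds.
#' @return numeric amplitudes.
#' @export
hrfAt <- function(hrf, t) {
  stats::approx(hrf@times, hrf@amplitudes, xout = t, yleft = 0,
                yright = 0)$y
}
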