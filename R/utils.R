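#' @keywords internal
#' @useDynLib physiophen, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Derive a child seed from a parent seed and an integer stream id.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 1009) %% 2147483629)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Sample skewness
#'
#' Third standardized moment, computed with the population (biased, n in the
#' denominator) convention. Returns 0 for degenerate (zero-variance) input.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return scalar skewness.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Sample excess kurtosis
#'
#' Fourth standardized moment minus 3 (population convention); 0 for
#' zero-variance input.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return scalar excess kurtosis.
#' @export
sample_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

# Shannon entropy (nats) of a histogram over x with Freedman-Diaconis bins
# (rule config-exposed through n_bins override).
hist_entropy <- function(x, n_bins = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  if (diff(range(x)) == 0) return(0)
  if (is.null(n_bins)) {
    iqr <- stats::IQR(x)
    if (iqr <= 0) {
      n_bins <- ceiling(log2(n)) + 1L  # Sturges fallback for degenerate IQR
    } else {
      bw <- 2 * iqr / n^(1 / 3)
      # cap: near-zero IQR with a wide range would request absurd bin counts
      n_bins <- min(1024L, max(1L, ceiling(diff(range(x)) / bw)))
    }
  }
  counts <- tabulate(
    pmin(n_bins, pmax(1L, findInterval(x, seq(min(x), max(x), length.out = n_bins + 1L),
                                       rightmost.closed = TRUE))),
    nbins = n_bins
  )
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

# Gini coefficient by mean absolute difference; 0 for a constant series.
gini_coef <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(0)
  xs <- sort(x)
  g <- sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * m)
  g
}

# Linear slope of x against its 1-based index.
index_slope <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2L) return(NA_real_)
  i <- seq_along(x)[ok]
  stats::cov(i, x[ok]) / stats::var(i)
}

# Lag-1 autocorrelation via Pearson correlation of (x_t, x_{t+1}).
lag1_autocor <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  if (stats::sd(x[-n]) == 0 || stats::sd(x[-1]) == 0) return(NA_real_)
  stats::cor(x[-n], x[-1])
}

# Local maxima of a numeric vector (strictly greater than both neighbours).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

`%||%` <- function(a, b) if (is.null(a)) b else a
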