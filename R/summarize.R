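# Stage 6: summary statistics of time-varying markers.

#' Summarize a time-varying marker series
#'
#' Computes the 16 summary statistics used to characterize a per-beat /
#' per-pulse / per-cycle marker over the region of interest: mean, median,
#' SD, mean absolute deviation, IQR, min, max, 25th/75th percentiles,
#' skewness, excess kurtosis, histogram Shannon entropy (Freedman--Diaconis
#' bins), linear slope against index, lag-1 autocorrelation, Gini
#' coefficient, and valid length. HRV-style scalar indices bypass this stage
#' (they are already aggregates).
#'
#' @param x numeric series (may contain `NA`).
#' @param n_bins optional histogram bin-count override for the entropy.
#' @return named numeric vector of 16 statistics; all `NA` (except
#'   `n_valid`) when fewer than 2 valid values remain.
#' @export
summarize_series <- function(x, n_bins = NULL) {
  nm <- c("mean", "median", "sd", "mad", "iqr", "min", "max", "p25", "p75",
          "skewness", "kurtosis", "entropy", "slope", "lag1_autocorr",
          "gini", "n_valid")
  out <- stats::setNames(rep(NA_real_, 16L), nm)
  v <- x[is.finite(x)]
  out["n_valid"] <- length(v)
  if (length(v) < 2L) return(out)
  out["mean"] <- mean(v)
  out["median"] <- stats::median(v)
  out["sd"] <- stats::sd(v)
  out["mad"] <- mean(abs(v - mean(v)))
  out["iqr"] <- stats::IQR(v)
  out["min"] <- min(v)
  out["max"] <- max(v)
  out["p25"] <- stats::quantile(v, 0.25, names = FALSE)
  out["p75"] <- stats::quantile(v, 0.75, names = FALSE)
  out["skewness"] <- sample_skewness(v)
  out["kurtosis"] <- sample_kurtosis(v)
  out["entropy"] <- hist_entropy(v, n_bins)
  out["slope"] <- index_slope(x)
  out["lag1_autocorr"] <- lag1_autocor(v)
  out["gini"] <- gini_coef(v)
  out
}

#' Retained summary statistics
#'
#' The five statistics kept per time-varying marker to limit redundancy while
#' covering central tendency (mean), quartile spread (p25/p75), asymmetry
#' (skewness) and complexity (entropy).
#'
#' @return character vector of statistic names.
#' @export
retained_stats <- function() c("mean", "p25", "p75", "skewness", "entropy")

#' Select the retained statistics from a full summary
#'
#' @param stats16 output of [summarize_series()].
#' @return named numeric vector of the 5 retained statistics.
#' @export
select_retained <- function(stats16) stats16[retained_stats()]

# Fast path used in bulk extraction: computes only the retained statistics.
summarize_retained <- function(x) {
  v <- x[is.finite(x)]
  if (length(v) < 2L) {
    return(stats::setNames(rep(NA_real_, 5L), retained_stats()))
  }
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  c(mean = mean(v), p25 = q[1], p75 = q[2],
    skewness = sample_skewness(v), entropy = hist_entropy(v))
}
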