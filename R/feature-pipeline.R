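# Feature pipeline: covariate encoding, outlier rejection, missingness
# filtering, imputation, variance and correlation filters, standardization.
# Step order is fixed: outliers -> missingness -> imputation -> variance ->
# correlation -> standardization.

#' Encode physiologic covariates as abnormality indicators
#'
#' qSOFA-style encoding: SBP <= 100 mmHg, respiratory rate >= 22 breaths/min,
#' GCS < 15, each coded 1 if abnormal, plus their composite sum (0-3).
#' Missing inputs yield missing indicators (and a missing composite).
#'
#' @param sbp systolic blood pressure, mmHg.
#' @param rr respiratory rate, breaths/min.
#' @param gcs Glasgow Coma Scale total (3-15).
#' @return data frame with `sbp_low`, `rr_high`, `gcs_low`, `composite`.
#' @export
encode_covariates <- function(sbp, rr, gcs) {
  if (any(gcs < 3 | gcs > 15, na.rm = TRUE)) stop("GCS must lie in [3, 15]")
  sbp_low <- as.numeric(sbp <= 100)
  rr_high <- as.numeric(rr >= 22)
  gcs_low <- as.numeric(gcs < 15)
  data.frame(sbp_low = sbp_low, rr_high = rr_high, gcs_low = gcs_low,
             composite = sbp_low + rr_high + gcs_low)
}

#' Mask extreme outlier cells
#'
#' Computes per-column z-scores on the observed values and sets cells with
#' `|z| > z_threshold` (strict) to `NA`. Constant columns are untouched.
#'
#' @param x numeric data frame / matrix.
#' @param z_threshold default 6.
#' @return list with `data` and `report` (masked-cell counts per column).
#' @export
reject_outliers <- function(x, z_threshold = 6) {
  x <- as.data.frame(x, check.names = FALSE)
  masked <- integer(0)
  for (j in seq_along(x)) {
    v <- x[[j]]
    if (!is.numeric(v)) next
    mu <- mean(v, na.rm = TRUE)
    sdv <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) next
    bad <- !is.na(v) & abs((v - mu) / sdv) > z_threshold
    if (any(bad)) {
      x[[j]][bad] <- NA
      masked[names(x)[j]] <- sum(bad)
    }
  }
  list(data = x, report = list(masked_cells = masked))
}

#' Drop columns with excessive missingness
#'
#' Columns with a missing fraction strictly greater than `max_frac` are
#' removed (15% missingness is kept, 16% dropped).
#'
#' @param x data frame.
#' @param max_frac default 0.15.
#' @return list with `data` and `report` (dropped columns and fractions).
#' @export
filter_missingness <- function(x, max_frac = 0.15) {
  x <- as.data.frame(x, check.names = FALSE)
  fr <- vapply(x, function(v) mean(is.na(v)), 0)
  drop <- names(fr)[fr > max_frac]
  list(data = x[, setdiff(names(x), drop), drop = FALSE],
       report = list(dropped = drop, missing_fraction = fr[drop]))
}

#' Drop near-constant columns
#'
#' A column is near-constant when its most frequent value occupies more than
#' `max_dominant` of the observations or its raw SD is below `sd_eps`.
#'
#' @param x data frame.
#' @param max_dominant default 0.99.
#' @param sd_eps default 1e-8.
#' @return list with `data` and `report`.
#' @export
filter_low_variance <- function(x, max_dominant = 0.99, sd_eps = 1e-8) {
  x <- as.data.frame(x, check.names = FALSE)
  drop <- character(0)
  for (j in names(x)) {
    v <- x[[j]]
    v <- v[!is.na(v)]
    if (!length(v)) { drop <- c(drop, j); next }
    sdv <- stats::sd(v)
    dom <- max(tabulate(match(v, unique(v)))) / length(v)
    if (!is.finite(sdv) || sdv < sd_eps || dom > max_dominant) drop <- c(drop, j)
  }
  list(data = x[, setdiff(names(x), drop), drop = FALSE],
       report = list(dropped = drop))
}

#' Iteratively remove highly correlated columns
#'
#' While any absolute pairwise Pearson correlation exceeds the threshold, the
#' member of the worst pair with the higher mean absolute correlation to all
#' remaining columns is dropped (ties broken toward the lexicographically
#' later name). Set `keep_higher_mean = TRUE` for the opposite rule.
#'
#' @param x complete-case numeric data frame.
#' @param threshold default 0.85.
#' @param keep_higher_mean retain (rather than drop) the higher-mean-|r|
#'   member of each offending pair.
#' @param exempt column names never dropped (e.g. covariate indicators).
#' @return list with `data` and `report` (drop order with triggering |r|).
#' @export
reduce_correlation <- function(x, threshold = 0.85, keep_higher_mean = FALSE,
                               exempt = character(0)) {
  x <- as.data.frame(x, check.names = FALSE)
  num <- names(x)[vapply(x, is.numeric, TRUE)]
  cand <- setdiff(num, exempt)
  if (length(cand) < 2L) return(list(data = x, report = list(dropped = character(0))))
  cm <- abs(stats::cor(x[cand], use = "pairwise.complete.obs"))
  diag(cm) <- 0
  cm[is.na(cm)] <- 0
  dropped <- character(0)
  rvals <- numeric(0)
  repeat {
    mx <- max(cm)
    if (mx <= threshold) break
    idx <- which(cm == mx, arr.ind = TRUE)[1, ]
    pair <- colnames(cm)[idx]
    mean_r <- colMeans(cm)[pair]
    pick <- if (keep_higher_mean) pair[which.min(mean_r)] else pair[which.max(mean_r)]
    if (mean_r[1] == mean_r[2]) pick <- max(pair)  # lexicographic tie-break
    dropped <- c(dropped, pick)
    rvals <- c(rvals, mx)
    keep <- setdiff(colnames(cm), pick)
    cm <- cm[keep, keep, drop = FALSE]
    if (ncol(cm) < 2L) break
  }
  list(data = x[, setdiff(names(x), dropped), drop = FALSE],
       report = list(dropped = dropped, abs_r = rvals))
}

#' Standardize columns to zero mean, unit variance
#'
#' @param x complete numeric data frame.
#' @param scaler optional stored scaler (from a previous call) to apply to
#'   new rows using the stored moments.
#' @return list with `data`, `scaler` (`center`, `scale`).
#' @export
standardize <- function(x, scaler = NULL) {
  x <- as.data.frame(x, check.names = FALSE)
  if (is.null(scaler)) {
    center <- vapply(x, mean, 0)
    scl <- vapply(x, stats::sd, 0)
    scl[!is.finite(scl) | scl == 0] <- 1
    scaler <- list(center = center, scale = scl)
  }
  out <- as.data.frame(
    sweep(sweep(as.matrix(x), 2, scaler$center[names(x)]), 2,
          scaler$scale[names(x)], "/"),
    check.names = FALSE)
  list(data = out, scaler = scaler)
}

#' Invert a standardization
#'
#' @param z standardized data frame.
#' @param scaler scaler returned by [standardize()].
#' @return data frame on the original scale.
#' @export
unstandardize <- function(z, scaler) {
  as.data.frame(
    sweep(sweep(as.matrix(z), 2, scaler$scale[colnames(z)], "*"), 2,
          scaler$center[colnames(z)], "+"),
    check.names = FALSE)
}

#' Run the full feature-cleaning pipeline
#'
#' Outlier rejection, missingness filtering, chained-equation imputation with
#' predictive mean matching, low-variance filtering, correlation reduction,
#' and standardization, with an accounting report per step. Covariate
#' indicator columns are exempt from the variance/correlation filters by
#' default (the composite correlates with its parts by construction).
#'
#' @param features numeric data frame (rows = patients).
#' @param covariates optional data frame from [encode_covariates()], appended
#'   after cleaning of the physiomarker block.
#' @param z_threshold,max_missing,cor_threshold step parameters.
#' @param exempt_covariates exempt indicator columns from variance and
#'   correlation filters.
#' @param seed imputation seed.
#' @return object of class `feature_pipeline_result`: `data` (standardized),
#'   `data_unscaled`, `scaler`, `report` (per-step drops), `seed`.
#' @export
run_feature_pipeline <- function(features, covariates = NULL, z_threshold = 6,
                                 max_missing = 0.15, cor_threshold = 0.85,
                                 exempt_covariates = TRUE, seed = 1L) {
  x <- as.data.frame(features, check.names = FALSE)
  stopifnot(!anyDuplicated(names(x)))
  n0 <- ncol(x)
  report <- list(n_initial = n0)

  s1 <- reject_outliers(x, z_threshold)
  report$outliers <- s1$report
  s2 <- filter_missingness(s1$data, max_missing)
  report$missingness <- s2$report
  # columns that are entirely missing cannot be imputed; account them here
  all_na <- names(s2$data)[vapply(s2$data, function(v) all(is.na(v)), TRUE)]
  report$all_missing <- list(dropped = all_na)
  x2 <- s2$data[, setdiff(names(s2$data), all_na), drop = FALSE]
  x3 <- impute_mice(x2, seed = seed)
  report$imputation <- attr(x3, "diagnostics")
  s4 <- filter_low_variance(x3)
  report$low_variance <- s4$report

  cov_names <- character(0)
  dat <- s4$data
  if (!is.null(covariates)) {
    cov_names <- names(covariates)
    stopifnot(nrow(covariates) == nrow(dat))
    dat <- cbind(dat, covariates)
  }
  exempt <- if (exempt_covariates) cov_names else character(0)
  s5 <- reduce_correlation(dat, cor_threshold, exempt = exempt)
  report$correlation <- s5$report
  s6 <- standardize(s5$data)
  report$n_final <- ncol(s6$data)

  structure(list(data = s6$data, data_unscaled = s5$data, scaler = s6$scaler,
                 report = report, seed = seed),
            class = "feature_pipeline_result")
}
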