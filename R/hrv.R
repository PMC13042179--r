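# Stage 5 (part): interval-dynamics battery -- time-domain, spectral, and
# nonlinear indices of an interval series (NN intervals, PPG pulse intervals,
# breath periods).

# ---- nonlinear building blocks ------------------------------------------
# The O(n^2) pair scans live in src/kernels.cpp.

#' Sample entropy
#'
#' SampEn(m, r): negative log of the conditional probability that sequences
#' matching for m points (Chebyshev distance <= r, self-matches excluded)
#' also match for m + 1 points. When no template pair matches, the
#' conventional finite upper bound `-log(2 / (N (N - 1)))` is returned
#' (N = number of templates) so that short, highly irregular series yield a
#' large but finite value.
#'
#' @param x numeric series.
#' @param m embedding dimension (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return scalar; 0 for degenerate (zero-variance) series.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  x <- x[is.finite(x)]
  if (length(x) < m + 2L) return(NA_real_)
  if (!is.finite(r) || r <= 0) return(0)
  ab <- cpp_sampen_counts(x, as.integer(m), r)
  N <- length(x) - m
  cap <- -log(2 / (N * (N - 1)))
  if (ab[2] == 0 || ab[1] == 0) return(cap)
  min(cap, -log(ab[1] / ab[2]))
}

# Approximate entropy (with self-matches), phi(m) - phi(m+1).
approx_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  x <- x[is.finite(x)]
  if (length(x) < m + 2L) return(NA_real_)
  if (!is.finite(r) || r <= 0) return(0)
  cpp_apen_phi(x, as.integer(m), r) - cpp_apen_phi(x, as.integer(m) + 1L, r)
}

# Fuzzy entropy: exponential membership exp(-(d/r)^2) on baseline-removed
# templates.
fuzzy_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  x <- x[is.finite(x)]
  if (length(x) < m + 2L) return(NA_real_)
  if (!is.finite(r) || r <= 0) return(0)
  a <- cpp_fuzzy_phi(x, as.integer(m) + 1L, r)
  b <- cpp_fuzzy_phi(x, as.integer(m), r)
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(NA_real_)
  -log(a / b)
}

# Composite multiscale sample entropy, scales 1..max_scale: for each scale
# average SampEn over all coarse-graining offsets, then average over scales.
cmse_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x), max_scale = 3L,
                         per_scale = FALSE) {
  x <- x[is.finite(x)]
  if (length(x) < (m + 2L) * max_scale) {
    return(if (per_scale) rep(NA_real_, max_scale) else NA_real_)
  }
  if (!is.finite(r) || r <= 0) {
    return(if (per_scale) rep(0, max_scale) else 0)
  }
  per <- vapply(seq_len(max_scale), function(tau) {
    vals <- vapply(seq_len(tau), function(off) {
      xi <- x[off:length(x)]
      ng <- floor(length(xi) / tau)
      if (ng < m + 2L) return(NA_real_)
      grained <- colMeans(matrix(xi[seq_len(ng * tau)], nrow = tau))
      sample_entropy(grained, m, r)
    }, 0)
    mean(vals, na.rm = TRUE)
  }, 0)
  if (per_scale) per else mean(per, na.rm = TRUE)
}

# Grassberger-Procaccia correlation dimension: least-squares slope of
# log C(rho) vs log rho in a mid-range scaling region, averaged over
# embedding dimensions 2..5.
correlation_dimension <- function(x, dims = 2:5) {
  x <- x[is.finite(x)]
  n0 <- length(x)
  if (n0 < max(dims) + 10L) return(NA_real_)
  if (stats::sd(x) == 0) return(0)
  slopes <- cpp_gp_slopes(x, as.integer(min(dims)), as.integer(max(dims)))
  mean(slopes, na.rm = TRUE)
}

#' Katz fractal dimension
#'
#' `KFD = log10(n) / (log10(n) + log10(d / L))` where `L` is the curve length
#' (sum of successive absolute differences), `d` the maximal distance from
#' the first point, and `n` the number of steps. Returns 1 for a straight
#' (including constant) series.
#'
#' @param x numeric series.
#' @return scalar >= 1.
#' @export
katz_fd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x) - 1L
  if (n < 2L) return(NA_real_)
  L <- sum(abs(diff(x)))
  d <- max(abs(x - x[1]))
  if (L == 0 || d == 0) return(1)
  log10(n) / (log10(n) + log10(d / L))
}

# ---- spectral (Lomb-Scargle on the tachogram) ---------------------------

# Classical Lomb-Scargle periodogram of (t, y) at frequencies f (Hz),
# in units of y-variance per Hz equivalent (unnormalized, scaled so that the
# band integral approximates the variance share).
lomb_power <- function(t, y, f) {
  y <- y - mean(y)
  n <- length(y)
  vapply(f, function(ff) {
    w <- 2 * pi * ff
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, 0)
}

# Band powers of an interval tachogram (intervals in ms). Powers are
# reported as normalized fractions: VLF/LF/HF relative to total band power
# (0.003-0.40 Hz), LFHF as the LF/HF ratio, and TP as the fraction of series
# variance recovered in the band.
tachogram_spectrum <- function(x_ms, bands = c(vlf = 0.003, lf = 0.04, hf = 0.15, top = 0.40)) {
  out <- c(TP = NA_real_, VLF = NA_real_, LF = NA_real_, HF = NA_real_,
           LFHF = NA_real_, LFnu = NA_real_, HFnu = NA_real_,
           peakLF = NA_real_, peakHF = NA_real_)
  n <- length(x_ms)
  if (n < 20L || stats::sd(x_ms) == 0) {
    if (n >= 2L && stats::sd(x_ms) == 0) out[] <- 0
    return(out)
  }
  t <- cumsum(x_ms) / 1000
  f <- seq(bands[1], bands[4], by = 0.002)
  P <- lomb_power(t, x_ms, f)
  df <- 0.002
  in_vlf <- f < bands[2]
  in_lf <- f >= bands[2] & f < bands[3]
  in_hf <- f >= bands[3]
  p_vlf <- sum(P[in_vlf]) * df
  p_lf <- sum(P[in_lf]) * df
  p_hf <- sum(P[in_hf]) * df
  tot <- p_vlf + p_lf + p_hf
  # Lomb power integrates to ~ n/2 * var / T ... normalize band total against
  # the series variance to obtain a dimensionless captured-variance fraction.
  dur <- t[n] - t[1]
  var_frac <- min(1, 2 * tot * dur / (n * stats::var(x_ms)))
  if (tot <= 0) return(out)
  c(TP = var_frac,
    VLF = p_vlf / tot, LF = p_lf / tot, HF = p_hf / tot,
    LFHF = if (p_hf > 0) p_lf / p_hf else NA_real_,
    LFnu = p_lf / max(p_lf + p_hf, .Machine$double.eps),
    HFnu = p_hf / max(p_lf + p_hf, .Machine$double.eps),
    peakLF = f[in_lf][which.max(P[in_lf])],
    peakHF = f[in_hf][which.max(P[in_hf])])
}

# ---- the battery ---------------------------------------------------------

#' Names of the interval-dynamics battery indices
#'
#' @param spectral include the spectral block (only meaningful for series
#'   that resolve the 0.003--0.40 Hz range).
#' @return character vector of index names.
#' @export
battery_names <- function(spectral = TRUE) {
  nm <- c("MeanNN", "MedianNN", "SDNN", "SDSD", "RMSSD", "CVNN", "CVSD",
          "pNN50", "pNN20", "MinNN", "MaxNN", "IQRNN", "MADNN", "HTI",
          "TP", "VLF", "LF", "HF", "LFHF", "LFnu", "HFnu", "peakLF", "peakHF",
          "ShanEn", "SampEn", "ApEn", "FuzzyEn", "MSEn1", "MSEn2", "MSEn3",
          "CMSEn", "CD", "KFD", "SD1", "SD2", "SD1SD2", "CSI", "CVI",
          "PIP", "IALS", "PSS", "PAS")
  if (!spectral) nm <- setdiff(nm, c("TP", "VLF", "LF", "HF", "LFHF",
                                     "LFnu", "HFnu", "peakLF", "peakHF"))
  nm
}

# Heart-rate fragmentation indices (acceleration/deceleration segments).
fragmentation_indices <- function(x) {
  d <- diff(x)
  d <- d[d != 0 | TRUE]
  n <- length(d)
  if (n < 3L) return(c(PIP = NA_real_, IALS = NA_real_, PSS = NA_real_, PAS = NA_real_))
  s <- sign(d)
  s[s == 0] <- 1
  flips <- sum(diff(s) != 0)
  pip <- 100 * flips / n
  r <- rle(as.vector(s))
  ials <- 1 / mean(r$lengths)
  pss <- 100 * sum(r$lengths[r$lengths < 3]) / n
  alt <- r$lengths == 1
  ra <- rle(alt)
  pas_runs <- ra$lengths[ra$values & ra$lengths >= 4]
  pas <- 100 * sum(pas_runs) / n
  c(PIP = pip, IALS = ials, PSS = pss, PAS = pas)
}

#' Interval-dynamics battery
#'
#' Computes the full set of time-domain, spectral, and nonlinear indices on
#' an interval series (milliseconds): moments and quantiles, pNN counts,
#' histogram triangular index, Lomb--Scargle band powers (normalized
#' fractions), histogram Shannon entropy, sample/approximate/fuzzy entropy,
#' (composite) multiscale entropy at scales 1--3, Grassberger--Procaccia
#' correlation dimension, Katz fractal dimension, Poincare geometry
#' (SD1/SD2/CSI/CVI) and heart-rate fragmentation.
#'
#' @param x_ms intervals in ms.
#' @param spectral include the Lomb--Scargle block (meaningful only for
#'   series long enough to resolve 0.003--0.40 Hz).
#' @return named numeric vector (see [battery_names()]).
#' @export
interval_battery <- function(x_ms, spectral = TRUE) {
  nm <- battery_names(spectral)
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  x <- x_ms[is.finite(x_ms)]
  n <- length(x)
  if (n < 10L) return(out)
  d <- diff(x)
  sdnn <- stats::sd(x)
  sdsd <- stats::sd(d)
  rmssd <- sqrt(mean(d^2))
  r_tol <- 0.2 * sdnn
  out["MeanNN"] <- mean(x)
  out["MedianNN"] <- stats::median(x)
  out["SDNN"] <- sdnn
  out["SDSD"] <- sdsd
  out["RMSSD"] <- rmssd
  out["CVNN"] <- sdnn / mean(x)
  out["CVSD"] <- rmssd / mean(x)
  out["pNN50"] <- 100 * mean(abs(d) > 50)
  out["pNN20"] <- 100 * mean(abs(d) > 20)
  out["MinNN"] <- min(x)
  out["MaxNN"] <- max(x)
  out["IQRNN"] <- stats::IQR(x)
  out["MADNN"] <- stats::mad(x)
  bin <- 7.8125
  out["HTI"] <- n / max(tabulate(pmax(1L, ceiling((x - min(x)) / bin + 1e-12)),
                                 nbins = max(1L, ceiling(diff(range(x)) / bin)) + 1L), 1)
  if (spectral) {
    sp <- tachogram_spectrum(x)
    out[names(sp)] <- sp
  }
  out["ShanEn"] <- hist_entropy(x)
  if (sdnn == 0) {
    out[c("SampEn", "ApEn", "FuzzyEn", "MSEn1", "MSEn2", "MSEn3", "CMSEn", "CD")] <- 0
    out["KFD"] <- 1
  } else {
    out["SampEn"] <- sample_entropy(x, 2L, r_tol)
    out["ApEn"] <- approx_entropy(x, 2L, r_tol)
    out["FuzzyEn"] <- fuzzy_entropy(x, 2L, r_tol)
    mse <- cmse_entropy(x, 2L, r_tol, 3L, per_scale = TRUE)
    out["MSEn1"] <- mse[1]; out["MSEn2"] <- mse[2]; out["MSEn3"] <- mse[3]
    out["CMSEn"] <- mean(mse, na.rm = TRUE)
    out["CD"] <- correlation_dimension(x)
    out["KFD"] <- katz_fd(x)
  }
  sd1 <- sqrt(0.5) * sdsd
  sd2 <- sqrt(max(0, 2 * sdnn^2 - 0.5 * sdsd^2))
  out["SD1"] <- sd1
  out["SD2"] <- sd2
  out["SD1SD2"] <- if (sd2 > 0) sd1 / sd2 else 0
  out["CSI"] <- if (sd1 > 0) sd2 / sd1 else 0
  out["CVI"] <- if (sd1 > 0 && sd2 > 0) log10(16 * sd1 * sd2) else 0
  out[c("PIP", "IALS", "PSS", "PAS")] <- fragmentation_indices(x)
  out
}

#' Filter an RR series to normal-to-normal (NN) intervals
#'
#' Removes intervals outside \[300, 2000\] ms and intervals whose change from
#' the previous interval exceeds 30% (a standard artifact rule; config
#' exposed).
#'
#' @param rr_ms RR intervals, ms.
#' @param bounds plausible interval range, ms.
#' @param max_rel_change successive-change limit (fraction).
#' @return filtered numeric vector.
#' @export
filter_nn <- function(rr_ms, bounds = c(300, 2000), max_rel_change = 0.3) {
  x <- rr_ms[is.finite(rr_ms) & rr_ms >= bounds[1] & rr_ms <= bounds[2]]
  if (length(x) < 2L) return(x)
  rel <- abs(diff(x)) / x[-length(x)]
  keep <- c(TRUE, rel <= max_rel_change)
  x[keep]
}

#' Scalar HRV indices of an NN interval series
#'
#' Applies NN filtering then the full interval battery; returns all indices
#' `NA` (with a `reason` attribute) when fewer than 10 intervals survive.
#'
#' @param rr_ms RR intervals, ms.
#' @param nn_filter apply [filter_nn()] first.
#' @return named numeric vector of HRV indices.
#' @export
compute_hrv <- function(rr_ms, nn_filter = TRUE) {
  nn <- if (nn_filter) filter_nn(rr_ms) else rr_ms[is.finite(rr_ms)]
  if (length(nn) < 10L) {
    out <- stats::setNames(rep(NA_real_, length(battery_names())), battery_names())
    attr(out, "reason") <- "fewer than 10 NN intervals after filtering"
    return(out)
  }
  interval_battery(nn, spectral = TRUE)
}
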