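# Stage 1-2 of the waveform interpreter: quality control and denoising.

#' Quality-control and resample a waveform record
#'
#' Flatline segments (rolling-window variance below epsilon), rail-clipping
#' runs, and amplitude outliers (|z| above threshold, masked and
#' interpolated) are detected per channel; each channel is then resampled to
#' its configured uniform rate. A channel whose usable fraction falls below
#' the floor is flagged low-quality; downstream extraction then reports
#' missing markers rather than failing.
#'
#' @param record a [waveform_record()].
#' @param rules list of QC settings: `z_threshold` (default 6),
#'   `flatline_window_s` (2), `flatline_eps` (1e-12), `clip_min_run_s` (0.2),
#'   `usable_floor` (0.5), `target_fs` (named vector of output rates, Hz;
#'   default keeps each channel's rate).
#' @return list with `record` (masked, resampled) and `report` (a
#'   `quality_report`: per-channel flatline/clipping/outlier/usable fractions
#'   and a `low_quality` flag).
#' @export
preprocess <- function(record, rules = list()) {
  stopifnot(inherits(record, "waveform_record"), length(record$channels) >= 1L)
  z_thr <- rules$z_threshold %||% 6
  fl_w <- rules$flatline_window_s %||% 2
  fl_eps <- rules$flatline_eps %||% 1e-12
  clip_run <- rules$clip_min_run_s %||% 0.2
  floor_q <- rules$usable_floor %||% 0.5
  target_fs <- rules$target_fs %||% NULL

  report <- list()
  for (nm in names(record$channels)) {
    ch <- record$channels[[nm]]
    x <- ch$x
    n <- length(x)
    fs <- ch$fs

    # flatline: centered rolling variance below epsilon
    w <- max(3L, round(fl_w * fs))
    flat <- rolling_var_below(x, w, fl_eps)

    # clipping: runs at the amplitude rails of at least clip_run seconds
    rng <- range(x)
    tol <- max(1e-12, diff(rng) * 1e-9)
    at_rail <- (x <= rng[1] + tol) | (x >= rng[2] - tol)
    clip <- mask_long_runs(at_rail, max(1L, round(clip_run * fs)))
    if (diff(rng) == 0) clip <- rep(FALSE, n)  # pure flatline, not clipping

    # amplitude outliers on non-flagged samples
    base_ok <- !flat & !clip
    mu <- mean(x[base_ok])
    sdv <- stats::sd(x[base_ok])
    out <- rep(FALSE, n)
    if (is.finite(sdv) && sdv > 0) out <- base_ok & abs((x - mu) / sdv) > z_thr
    if (any(out) && any(!out)) {
      idx <- which(!out)
      x[out] <- stats::approx(idx, x[idx], xout = which(out), rule = 2)$y
    }

    mask_bad <- flat | clip | out
    usable <- 1 - mean(mask_bad)
    rep_ch <- list(flatline_fraction = mean(flat),
                   clipping_fraction = mean(clip),
                   outlier_fraction = mean(out),
                   usable_fraction = usable,
                   low_quality = usable < floor_q)

    # resample to configured uniform frequency
    fs_new <- if (!is.null(target_fs) && nm %in% names(target_fs)) target_fs[[nm]] else fs
    if (fs_new != fs) {
      dur <- n / fs
      n_new <- floor(dur * fs_new)
      t_old <- (seq_len(n) - 1L) / fs
      t_new <- (seq_len(n_new) - 1L) / fs_new
      x <- stats::approx(t_old, x, xout = t_new, rule = 2)$y
      q_new <- !(stats::approx(t_old, as.numeric(mask_bad), xout = t_new,
                               method = "constant", rule = 2)$y > 0)
    } else {
      q_new <- !mask_bad
    }
    record$channels[[nm]]$x <- x
    record$channels[[nm]]$fs <- fs_new
    record$quality[[nm]] <- q_new
    report[[nm]] <- rep_ch
  }
  list(record = record, report = structure(report, class = "quality_report"))
}

# TRUE where the centered rolling variance over window w falls below eps.
rolling_var_below <- function(x, w, eps) {
  n <- length(x)
  if (n < w) return(rep(stats::var(x) < eps, n))
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  s <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  s2 <- cs2[(w + 1):(n + 1)] - cs2[1:(n - w + 1)]
  v <- pmax(0, s2 / w - (s / w)^2)
  low <- v < eps                       # one value per window start
  flat <- rep(FALSE, n)
  # expand each low window across its span
  starts <- which(low)
  if (length(starts)) {
    d <- rep(0L, n + 1L)
    d[starts] <- d[starts] + 1L
    d[pmin(n + 1L, starts + w)] <- d[pmin(n + 1L, starts + w)] - 1L
    flat <- cumsum(d[seq_len(n)]) > 0L
  }
  flat
}

# Keep only TRUE runs of at least min_run samples.
mask_long_runs <- function(flag, min_run) {
  r <- rle(flag)
  r$values <- r$values & r$lengths >= min_run
  inverse.rle(r)
}

# Per-channel band-pass edges (Hz) used by denoise().
default_bands <- function() {
  list(ecg = c(0.5, 40), ppg = c(0.5, 8), resp = c(0.1, 0.5), edr = c(0.1, 0.5))
}

#' Denoise a preprocessed record
#'
#' A conservative median-filter despiking pass (samples further than
#' `spike_sd` robust SDs from a ~0.2 s running median are replaced by that
#' median) followed by a zero-phase Butterworth band-pass with
#' channel-specific edges (ECG 0.5--40 Hz, PPG 0.5--8 Hz, RESP 0.1--0.5 Hz).
#' Out-of-band tones are attenuated by >= 20 dB and in-band tones preserved
#' within 3 dB (an octave or more from the edges).
#'
#' @param record a preprocessed [waveform_record()].
#' @param bands named list of `c(low, high)` Hz per channel; defaults above.
#' @param order Butterworth order (doubled in effect by forward-backward
#'   filtering).
#' @param spike_sd despiking threshold in SDs (large by design so QRS
#'   complexes survive).
#' @return the filtered record; a channel shorter than three filter transients
#'   is marked unusable in its quality mask.
#' @export
denoise <- function(record, bands = default_bands(), order = 4, spike_sd = 8) {
  stopifnot(inherits(record, "waveform_record"))
  for (nm in names(record$channels)) {
    ch <- record$channels[[nm]]
    band <- bands[[nm]]
    if (is.null(band)) next
    x <- ch$x
    fs <- ch$fs
    n <- length(x)
    min_len <- 3L * ceiling(fs / band[1])
    if (n < min_len) {
      record$quality[[nm]] <- rep(FALSE, n)
      next
    }
    record$channels[[nm]]$dc <- mean(x)   # DC level, removed by the band-pass
    # despike
    k <- max(3L, round(0.2 * fs))
    if (k %% 2L == 0L) k <- k + 1L
    med <- stats::runmed(x, k)
    resid <- x - med
    thr <- spike_sd * stats::sd(x)
    if (is.finite(thr) && thr > 0) {
      spikes <- abs(resid) > thr
      x[spikes] <- med[spikes]
    }
    # zero-phase band-pass as a high-pass/low-pass cascade: the high-pass
    # edge sits at a tiny normalized frequency where high orders are
    # numerically fragile, so it gets order 2; the low-pass keeps the full
    # order (stop-band attenuation is doubled again by forward-backward
    # filtering)
    ny <- fs / 2
    lo <- band[1] / ny
    hi <- min(band[2] / ny, 0.99)
    x0 <- x
    hp <- signal::butter(2, lo, type = "high")
    x <- signal::filtfilt(hp, x)
    lp <- signal::butter(order, hi, type = "low")
    x <- signal::filtfilt(lp, x)
    if (!all(is.finite(x))) {           # numerically unstable: fall back
      bf <- signal::butter(1, c(lo, hi), type = "pass")
      x <- signal::filtfilt(bf, x0)
    }
    record$channels[[nm]]$x <- x
  }
  record
}
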