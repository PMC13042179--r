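# Stage 3-4 of the waveform interpreter: derived signals and fiducial points.

#' Derive secondary signals: EDR, VPG, APG
#'
#' ECG-derived respiration (EDR) interpolates per-beat R-wave amplitudes onto
#' a uniform time base (cubic spline, 4 Hz); the velocity and acceleration
#' plethysmograms are smoothed first/second Savitzky-Golay derivatives of the
#' PPG scaled by its sampling rate.
#'
#' @param record a denoised [waveform_record()].
#' @param rpeaks integer sample indices of ECG R peaks.
#' @param edr_fs output rate of the EDR channel, Hz.
#' @return named list of channels; `vpg`/`apg` absent when there is no PPG,
#'   `edr` absent with fewer than 3 R peaks.
#' @export
derive_signals <- function(record, rpeaks, edr_fs = 4) {
  out <- list()
  if (!is.null(record$channels$ecg) && length(rpeaks) >= 3L) {
    ecg <- record$channels$ecg
    t_r <- (rpeaks - 1L) / ecg$fs
    amp <- ecg$x[rpeaks]
    t_new <- seq(t_r[1], t_r[length(t_r)], by = 1 / edr_fs)
    edr <- stats::spline(t_r, amp, xout = t_new)$y
    out$edr <- list(x = edr, fs = edr_fs, units = record$channels$ecg$units)
  }
  if (!is.null(record$channels$ppg)) {
    ppg <- record$channels$ppg
    nwin <- max(5L, round(ppg$fs * 0.07))
    if (nwin %% 2L == 0L) nwin <- nwin + 1L
    # central Savitzky-Golay derivative kernels applied as a plain FIR
    sg1 <- signal::sgolay(p = 3, n = nwin, m = 1)[(nwin + 1L) %/% 2L, ]
    sg2 <- signal::sgolay(p = 3, n = nwin, m = 2)[(nwin + 1L) %/% 2L, ]
    vpg <- cpp_fir_centered(ppg$x, sg1) * ppg$fs
    apg <- cpp_fir_centered(ppg$x, sg2) * ppg$fs^2
    out$vpg <- list(x = vpg, fs = ppg$fs, units = paste0(ppg$units, "/s"))
    out$apg <- list(x = apg, fs = ppg$fs, units = paste0(ppg$units, "/s^2"))
  }
  out
}

# R-peak detection: derivative -> squaring -> moving-window integration with
# an adaptive threshold and a 200 ms refractory period; peak positions refined
# on the input signal.
detect_rpeaks <- function(x, fs, refractory_s = 0.2) {
  n <- length(x)
  if (n < fs) return(integer(0))
  d <- c(0, diff(x)) * fs
  sq <- d^2
  w <- max(3L, as.integer(round(0.15 * fs)))
  cs <- cumsum(c(0, sq))
  h1 <- w %/% 2L
  lo <- pmax(0L, seq_len(n) - h1 - 1L)
  hi <- pmin(n, seq_len(n) + (w - h1 - 1L))
  integ <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  thr <- 0.2 * stats::quantile(integ, 0.995)
  above <- integ > thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  half <- round(0.06 * fs)
  peaks <- apply(regions, 1, function(rg) {
    i0 <- max(1L, rg[1] - half)
    i1 <- min(n, rg[2] + half)
    i0 + which.max(x[i0:i1]) - 1L
  })
  peaks <- sort(unique(peaks))
  # refractory: drop the smaller of any pair closer than refractory_s
  min_gap <- round(refractory_s * fs)
  keep <- rep(TRUE, length(peaks))
  i <- 2L
  while (i <= length(peaks)) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    if (peaks[i] - peaks[prev] < min_gap) {
      if (x[peaks[i]] > x[peaks[prev]]) keep[prev] <- FALSE else keep[i] <- FALSE
    }
    i <- i + 1L
  }
  peaks[keep]
}

# QRS onset/offset: where the integrated energy falls below a fraction of the
# local peak energy around each R peak.
qrs_bounds <- function(x, fs, rpeaks) {
  half <- as.integer(round(0.08 * fs))
  n <- length(x)
  t(vapply(as.integer(rpeaks), function(p) {
    c(max(1L, p - half), min(n, p + half))
  }, integer(2)))
}

# PPG pulse delineation on denoised PPG + derivatives.
delineate_ppg <- function(ppg, vpg, apg, fs) {
  n <- length(ppg)
  # main upstrokes: VPG maxima above an adaptive threshold
  v_thr <- 0.4 * stats::quantile(vpg, 0.98)
  cand <- local_maxima(vpg)
  cand <- cand[vpg[cand] > v_thr]
  if (length(cand) < 2L) return(NULL)
  # refractory on upstrokes (0.35 s)
  min_gap <- round(0.35 * fs)
  keep <- rep(TRUE, length(cand))
  for (i in 2:length(cand)) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    if (cand[i] - cand[prev] < min_gap) {
      if (vpg[cand[i]] > vpg[cand[prev]]) keep[prev] <- FALSE else keep[i] <- FALSE
    }
  }
  up <- cand[keep]
  look <- as.integer(round(0.25 * fs))
  onsets <- vapply(as.integer(up), function(u) {
    i0 <- max(1L, u - look)
    i0 + which.min(ppg[i0:u]) - 1L
  }, integer(1))
  pulses <- list()
  edge <- round(0.4 * fs)   # zero-phase filter transients live at the edges
  for (k in seq_len(length(onsets) - 1L)) {
    on <- onsets[k]
    off <- onsets[k + 1L]
    if (on <= edge || off >= n - edge) next
    if (off - on < round(0.25 * fs)) next
    seg <- on:off
    sys <- on + which.max(ppg[seg]) - 1L
    if (sys <= on || sys >= off) next
    dur <- off - on
    w0 <- on + round(0.40 * dur)
    w1 <- on + round(0.70 * dur)
    w0 <- max(w0, sys + 2L)
    notch <- NA_integer_
    dias <- NA_integer_
    if (w1 > w0 + 2L) {
      win <- w0:w1
      # primary: upward VPG zero crossing (local PPG minimum = notch)
      zc <- win[vpg[win] <= 0 & c(vpg[(w0 + 1L):w1], Inf) > 0]
      zc <- zc[zc < w1]
      if (length(zc)) {
        notch <- zc[1]
      } else {
        # fallback: slowest-decay inflection (interior VPG local maximum =
        # deceleration hump of the decay). As the diastolic wave weakens,
        # the vanishing PPG local minimum merges with this inflection, so
        # the estimate stays continuous across the detectability boundary;
        # a featureless exponential decay has no interior VPG maximum and
        # yields no notch.
        lmx <- local_maxima(vpg[win])
        if (length(lmx)) notch <- win[lmx[which.max(vpg[win][lmx])]]
      }
      if (!is.na(notch) && notch < off - 2L) {
        post <- (notch + 1L):min(off, notch + round(0.25 * dur))
        pm <- local_maxima(ppg[post])
        if (length(pm)) dias <- post[pm[1]]
      }
    }
    pulses[[length(pulses) + 1L]] <-
      c(onset = on, sys = sys, notch = notch, dias = dias, offset = off)
  }
  if (!length(pulses)) return(NULL)
  as.data.frame(do.call(rbind, pulses))
}

# Respiratory transitions: zero crossings of the mean-removed signal, with
# per-cycle extrema (troughs and peaks).
delineate_resp <- function(x, fs) {
  xm <- x - mean(x)
  s <- sign(xm)
  s[s == 0] <- 1
  up <- which(diff(s) > 0) + 1L
  down <- which(diff(s) < 0) + 1L
  troughs <- integer(0)
  peaks <- integer(0)
  if (length(up) >= 2L) {
    for (k in seq_len(length(up) - 1L)) {
      seg <- up[k]:up[k + 1L]
      peaks <- c(peaks, seg[which.max(xm[seg])])
    }
  }
  if (length(down) >= 2L) {
    for (k in seq_len(length(down) - 1L)) {
      seg <- down[k]:down[k + 1L]
      troughs <- c(troughs, seg[which.min(xm[seg])])
    }
  }
  list(up = up, down = down, peaks = peaks, troughs = troughs)
}

#' Delineate fiducial points in all channels
#'
#' ECG R peaks (derivative--square--integrate with adaptive threshold and
#' 200 ms refractory), PPG pulse landmarks (onset/foot at the minimum
#' preceding each main VPG upstroke, systolic peak, dicrotic notch via the
#' first upward VPG zero crossing within 40--70% of the pulse -- with the
#' slowest-decay inflection as a continuous fallback -- diastolic peak,
#' offset), and respiratory transitions (zero crossings of the mean-removed
#' RESP signal).
#'
#' @param record a denoised [waveform_record()].
#' @param derived optional output of [derive_signals()]; computed on demand.
#' @return object of class `fiducial_set`: `ecg` (list with `r`, `qrs`),
#'   `ppg` (data frame of pulse index tuples), `resp` (transition lists).
#' @export
delineate <- function(record, derived = NULL) {
  out <- list(ecg = NULL, ppg = NULL, resp = NULL)
  if (!is.null(record$channels$ecg)) {
    ecg <- record$channels$ecg
    r <- detect_rpeaks(ecg$x, ecg$fs)
    out$ecg <- list(r = r, qrs = qrs_bounds(ecg$x, ecg$fs, r))
  }
  if (!is.null(record$channels$ppg)) {
    if (is.null(derived) || is.null(derived$vpg)) {
      derived <- c(derived, derive_signals(record, out$ecg$r %||% integer(0)))
    }
    ppg <- record$channels$ppg
    out$ppg <- delineate_ppg(ppg$x, derived$vpg$x, derived$apg$x, ppg$fs)
  }
  if (!is.null(record$channels$resp)) {
    resp <- record$channels$resp
    out$resp <- delineate_resp(resp$x, resp$fs)
  }
  structure(out, class = "fiducial_set")
}
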