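# Stage 5 (part): PPG morphology/timing markers, derivative-waveform markers,
# ECG-PPG coupling, and the interbeat covariance spectrum.

# Width of a pulse at a given fraction of the AC amplitude above onset level,
# with linear interpolation at the crossings. Returns ms, or NA.
pulse_width_at <- function(x, onset, sys, offset, frac, fs) {
  level <- x[onset] + frac * (x[sys] - x[onset])
  up <- onset:sys
  dn <- sys:offset
  iu <- which(x[up] >= level)
  if (!length(iu)) return(NA_real_)
  i1 <- up[iu[1]]
  t_left <- if (i1 == onset) as.numeric(i1) else {
    i0 <- i1 - 1L
    i0 + (level - x[i0]) / (x[i1] - x[i0])
  }
  id <- which(x[dn] < level)
  t_right <- if (!length(id)) as.numeric(offset) else {
    i1r <- dn[id[1]]
    i0r <- i1r - 1L
    if (x[i1r] == x[i0r]) as.numeric(i1r) else i0r + (x[i0r] - level) / (x[i0r] - x[i1r])
  }
  (t_right - t_left) / fs * 1000
}

# trapezoidal area of (x - baseline) between two sample indices, in ms * amp
trapz_area <- function(x, i0, i1, baseline, fs) {
  seg <- x[i0:i1] - baseline
  sum((seg[-1] + seg[-length(seg)]) / 2) / fs * 1000
}

#' Per-pulse PPG morphology and timing markers
#'
#' Computes, for every delineated pulse: AC amplitude, normalized
#' onset-to-systolic and systolic-to-offset areas, pulse widths at 25/50/75%
#' of the AC amplitude, slopes, timing fractions, dicrotic-notch and
#' diastolic-wave measures, perfusion index, derivative-waveform (VPG/APG)
#' markers, pulse-arrival times against ECG R peaks, and the eigenvalues of
#' the covariance matrix of pulses resampled to a common length.
#'
#' @param record denoised [waveform_record()] with a `ppg` channel.
#' @param fiducials a `fiducial_set` with delineated PPG pulses.
#' @param rpeaks ECG R-peak indices (ECG sampling rate), for coupling markers.
#' @param derived output of [derive_signals()] (VPG/APG); recomputed if NULL.
#' @param resample_len common length for the interbeat covariance (100).
#' @param n_eig number of leading eigenvalues reported.
#' @return list with `series` (named list of per-pulse numeric vectors),
#'   `eig` (named eigenvalue vector), `pulse_intervals_ms` (onset-to-onset).
#' @export
compute_ppg_markers <- function(record, fiducials, rpeaks = integer(0),
                                derived = NULL, resample_len = 100L, n_eig = 10L) {
  empty <- list(series = list(), eig = stats::setNames(rep(NA_real_, n_eig),
                                                       paste0("eigval", seq_len(n_eig))),
                pulse_intervals_ms = numeric(0))
  pul <- fiducials$ppg
  if (is.null(pul) || nrow(pul) < 5L) return(empty)
  ppg <- record$channels$ppg
  x <- ppg$x
  fs <- ppg$fs
  if (is.null(derived) || is.null(derived$vpg)) {
    derived <- derive_signals(record, rpeaks)
  }
  vpg <- derived$vpg$x
  apg <- derived$apg$x
  dc0 <- ppg$dc %||% 0                     # pre-band-pass DC level

  np <- nrow(pul)
  ser <- function() rep(NA_real_, np)
  s <- list(PPG_A_AC = ser(), PPG_A_sys = ser(), PPG_A_dc = ser(),
            PPG_AUCos = ser(), PPG_AUCso = ser(), PPG_AUCos_nu = ser(),
            PPG_AUCso_nu = ser(), PPG_AUC_ratio = ser(),
            PPG_PW_25 = ser(), PPG_PW_50 = ser(), PPG_PW_75 = ser(),
            PPG_width_ratio = ser(), PPG_mean_slope_os = ser(),
            PPG_mean_slope_so = ser(), PPG_rise_time = ser(),
            PPG_decay_time = ser(), PPG_pulse_duration = ser(),
            PPG_sys_time_frac = ser(), PPG_notch_time_frac = ser(),
            PPG_notch_depth = ser(), PPG_notch_to_offset = ser(),
            PPG_dias_amp_ratio = ser(), PPG_perfusion_index = ser(),
            PPG_pulse_interval = ser(),
            VPG_max = ser(), VPG_min = ser(), VPG_ratio = ser(),
            VPG_max_time = ser(), VPG_min_time = ser(),
            APG_a = ser(), APG_b = ser(), APG_b_a_ratio = ser(),
            APG_a_time = ser(), APG_b_time = ser(),
            PAT_ms = ser(), PAT_sys_ms = ser(), PTT_notch_ms = ser())

  mats <- matrix(NA_real_, np, resample_len)
  r_times <- if (length(rpeaks)) (rpeaks - 1L) / record$channels$ecg$fs else numeric(0)
  med_ibi <- if (length(r_times) > 2L) stats::median(diff(r_times)) else 1.0

  for (k in seq_len(np)) {
    on <- pul$onset[k]; sy <- pul$sys[k]; off <- pul$offset[k]
    if (!(on < sy && sy < off)) next
    ac <- x[sy] - x[on]
    if (!is.finite(ac) || ac <= 0) next
    dur_ms <- (off - on) / fs * 1000
    s$PPG_A_AC[k] <- ac
    s$PPG_A_sys[k] <- x[sy]
    s$PPG_A_dc[k] <- dc0 + x[on]
    a_os <- trapz_area(x, on, sy, x[on], fs)
    a_so <- trapz_area(x, sy, off, x[on], fs)
    s$PPG_AUCos[k] <- a_os
    s$PPG_AUCso[k] <- a_so
    s$PPG_AUCos_nu[k] <- a_os / (dur_ms * ac)
    s$PPG_AUCso_nu[k] <- a_so / (dur_ms * ac)
    s$PPG_AUC_ratio[k] <- if (a_so != 0) a_os / a_so else NA_real_
    s$PPG_PW_25[k] <- pulse_width_at(x, on, sy, off, 0.25, fs)
    s$PPG_PW_50[k] <- pulse_width_at(x, on, sy, off, 0.50, fs)
    s$PPG_PW_75[k] <- pulse_width_at(x, on, sy, off, 0.75, fs)
    if (is.finite(s$PPG_PW_25[k]) && is.finite(s$PPG_PW_75[k]) && s$PPG_PW_75[k] > 0) {
      s$PPG_width_ratio[k] <- s$PPG_PW_25[k] / s$PPG_PW_75[k]
    }
    rise_ms <- (sy - on) / fs * 1000
    decay_ms <- (off - sy) / fs * 1000
    s$PPG_rise_time[k] <- rise_ms
    s$PPG_decay_time[k] <- decay_ms
    s$PPG_pulse_duration[k] <- dur_ms
    s$PPG_sys_time_frac[k] <- rise_ms / dur_ms
    s$PPG_mean_slope_os[k] <- ac / rise_ms
    s$PPG_mean_slope_so[k] <- ac / decay_ms
    dc_lvl <- abs(dc0 + x[on])
    s$PPG_perfusion_index[k] <- if (dc_lvl > 0.05 * ac) ac / dc_lvl else NA_real_
    no <- pul$notch[k]
    if (!is.na(no)) {
      s$PPG_notch_time_frac[k] <- (no - on) / (off - on)
      s$PPG_notch_depth[k] <- (x[sy] - x[no]) / ac
      s$PPG_notch_to_offset[k] <- (off - no) / fs * 1000
    }
    di <- pul$dias[k]
    if (!is.na(di)) s$PPG_dias_amp_ratio[k] <- (x[di] - x[on]) / ac
    # derivative waveform markers within the pulse
    seg <- on:off
    vseg <- vpg[seg]
    s$VPG_max[k] <- max(vseg)
    s$VPG_min[k] <- min(vseg)
    s$VPG_ratio[k] <- if (max(vseg) > 0) abs(min(vseg)) / max(vseg) else NA_real_
    s$VPG_max_time[k] <- (which.max(vseg) - 1L) / fs * 1000
    s$VPG_min_time[k] <- (which.min(vseg) - 1L) / fs * 1000
    early <- on:min(off, on + ceiling(0.3 * (off - on)))
    aseg <- apg[early]
    ia <- which.max(aseg)
    s$APG_a[k] <- aseg[ia]
    s$APG_a_time[k] <- (ia - 1L) / fs * 1000
    post_a <- (on + ia):min(off, on + ceiling(0.5 * (off - on)))
    if (length(post_a) > 2L) {
      ib <- which.min(apg[post_a])
      s$APG_b[k] <- apg[post_a][ib]
      s$APG_b_time[k] <- (post_a[ib] - on) / fs * 1000
      if (s$APG_a[k] != 0) s$APG_b_a_ratio[k] <- s$APG_b[k] / s$APG_a[k]
    }
    # coupling: previous R peak within one cardiac cycle
    if (length(r_times)) {
      t_on <- (on - 1L) / fs
      prev <- r_times[r_times < t_on & r_times > t_on - 1.8 * med_ibi]
      if (length(prev)) {
        tr <- prev[length(prev)]
        s$PAT_ms[k] <- (t_on - tr) * 1000
        s$PAT_sys_ms[k] <- ((sy - 1L) / fs - tr) * 1000
        if (!is.na(no)) s$PTT_notch_ms[k] <- ((no - 1L) / fs - tr) * 1000
      }
    }
    # resampled, amplitude-normalized pulse for the covariance spectrum
    u <- seq(on, off, length.out = resample_len)
    pr <- stats::approx(seg, x[seg], xout = u)$y
    mats[k, ] <- (pr - x[on]) / ac
  }

  ok <- stats::complete.cases(mats)
  eig <- stats::setNames(rep(NA_real_, n_eig), paste0("eigval", seq_len(n_eig)))
  if (sum(ok) >= 5L) {
    cv <- stats::cov(mats[ok, , drop = FALSE])
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    eig[] <- ev[seq_len(n_eig)]
  }

  onsets_t <- (pul$onset - 1L) / fs
  s$PPG_pulse_interval <- c(NA_real_, diff(onsets_t) * 1000)
  list(series = s, eig = eig, pulse_intervals_ms = diff(onsets_t) * 1000)
}
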