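# Stage 5 (part): respiratory dynamics from RESP (and EDR) channels, and
# per-beat ECG wave series.

# Cycle analysis shared by RESP and EDR: breathing periods, inspiration
# (trough -> peak) and expiration (peak -> trough) durations, I:E ratio,
# instantaneous rate, amplitude, half-amplitude width and slopes.
cycle_markers <- function(x, fs, fid, prefix = "RESP") {
  troughs <- fid$troughs
  peaks <- fid$peaks
  nul <- stats::setNames(
    rep(list(numeric(0)), 11),
    paste0(prefix, "_", c("breath_period", "insp_duration", "exp_duration",
                          "ie_ratio", "inst_rate", "breath_amplitude",
                          "breath_width50", "insp_slope", "exp_slope",
                          "asymmetry", "ti_ttot")))
  if (length(troughs) < 3L || length(peaks) < 2L) return(nul)
  out <- nul
  n_cyc <- length(troughs) - 1L
  for (nm in names(out)) out[[nm]] <- rep(NA_real_, n_cyc)
  for (k in seq_len(n_cyc)) {
    t0 <- troughs[k]; t1 <- troughs[k + 1L]
    pk <- peaks[peaks > t0 & peaks < t1]
    if (!length(pk)) next
    pk <- pk[which.max(x[pk])]
    period <- (t1 - t0) / fs
    insp <- (pk - t0) / fs
    expd <- (t1 - pk) / fs
    amp <- x[pk] - x[t0]
    out[[paste0(prefix, "_breath_period")]][k] <- period
    out[[paste0(prefix, "_insp_duration")]][k] <- insp
    out[[paste0(prefix, "_exp_duration")]][k] <- expd
    out[[paste0(prefix, "_ie_ratio")]][k] <- insp / expd
    out[[paste0(prefix, "_inst_rate")]][k] <- 60 / period
    out[[paste0(prefix, "_breath_amplitude")]][k] <- amp
    out[[paste0(prefix, "_insp_slope")]][k] <- amp / insp
    out[[paste0(prefix, "_exp_slope")]][k] <- amp / expd
    out[[paste0(prefix, "_asymmetry")]][k] <- (insp - expd) / period
    out[[paste0(prefix, "_ti_ttot")]][k] <- insp / period
    half <- x[t0] + 0.5 * amp
    seg <- t0:t1
    above <- which(x[seg] >= half)
    if (length(above) > 1L) {
      out[[paste0(prefix, "_breath_width50")]][k] <- (max(above) - min(above)) / fs
    }
  }
  out
}

#' Per-cycle respiratory markers
#'
#' Breath period, inspiration/expiration durations (trough to peak and peak
#' to trough), I:E ratio, instantaneous rate, amplitude, half-amplitude width
#' and slopes for every respiratory cycle. Requires at least 3 cycles.
#'
#' @param record denoised [waveform_record()] with a `resp` channel.
#' @param fiducials a `fiducial_set` with respiratory transitions.
#' @return named list of per-cycle numeric vectors (empty when < 3 cycles).
#' @export
compute_resp_markers <- function(record, fiducials) {
  if (is.null(record$channels$resp) || is.null(fiducials$resp)) return(list())
  cycle_markers(record$channels$resp$x, record$channels$resp$fs,
                fiducials$resp, prefix = "RESP")
}

# EDR cycle markers (respiration reconstructed from R-amplitude modulation).
compute_edr_markers <- function(edr_channel) {
  if (is.null(edr_channel) || length(edr_channel$x) < 12L) return(list())
  fid <- delineate_resp(edr_channel$x, edr_channel$fs)
  out <- cycle_markers(edr_channel$x, edr_channel$fs, fid, prefix = "EDR")
  out[c("EDR_breath_period", "EDR_inst_rate", "EDR_ie_ratio", "EDR_breath_amplitude")]
}

# Per-beat ECG wave series measured around each R peak on the denoised ECG.
compute_ecg_beat_series <- function(record, rpeaks) {
  nul <- stats::setNames(rep(list(numeric(0)), 13),
                         paste0("ECG_", c("rr_ms", "hr_bpm", "r_amp", "p_amp",
                                          "q_amp", "s_amp", "t_amp",
                                          "qrs_duration", "pr_interval",
                                          "rt_ratio", "rr_ratio",
                                          "st_level", "tpeak_time")))
  if (length(rpeaks) < 10L) return(nul)
  ecg <- record$channels$ecg
  x <- ecg$x
  fs <- ecg$fs
  n <- length(x)
  nb <- length(rpeaks)
  rr <- diff(rpeaks) / fs * 1000
  win <- function(p, a, b) {
    i0 <- max(1L, p + round(a * fs)); i1 <- min(n, p + round(b * fs))
    if (i0 > i1) return(integer(0))
    i0:i1
  }
  s <- nul
  for (nm in names(s)) s[[nm]] <- rep(NA_real_, nb)
  s$ECG_rr_ms <- c(NA_real_, rr)
  s$ECG_hr_bpm <- c(NA_real_, 60000 / rr)
  s$ECG_rr_ratio <- c(NA_real_, NA_real_, rr[-1] / rr[-length(rr)])
  for (k in seq_len(nb)) {
    p <- rpeaks[k]
    s$ECG_r_amp[k] <- x[p]
    wq <- win(p, -0.06, -0.01)
    ws <- win(p, 0.01, 0.08)
    wp <- win(p, -0.30, -0.10)
    wt <- win(p, 0.12, 0.42)
    if (length(wq)) s$ECG_q_amp[k] <- min(x[wq])
    if (length(ws)) s$ECG_s_amp[k] <- min(x[ws])
    if (length(wp)) {
      ip <- wp[which.max(x[wp])]
      s$ECG_p_amp[k] <- x[ip]
      s$ECG_pr_interval[k] <- (p - ip) / fs * 1000
    }
    if (length(wt)) {
      it <- wt[which.max(x[wt])]
      s$ECG_t_amp[k] <- x[it]
      s$ECG_tpeak_time[k] <- (it - p) / fs * 1000
      s$ECG_rt_ratio[k] <- x[it] / x[p]
    }
    wst <- win(p, 0.08, 0.12)
    if (length(wst)) s$ECG_st_level[k] <- mean(x[wst])
    if (length(wq) && length(ws)) {
      s$ECG_qrs_duration[k] <- (ws[which.min(x[ws])] - wq[which.min(x[wq])]) / fs * 1000
    }
  }
  s
}
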