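# The physiomarker catalog: a data-driven manifest of every marker the
# interpreter emits. Scalar markers map to one feature column; time-varying
# markers expand into the five retained summary statistics.

ppg_series_names <- function() {
  c("PPG_A_AC", "PPG_A_sys", "PPG_A_dc", "PPG_AUCos", "PPG_AUCso",
    "PPG_AUCos_nu", "PPG_AUCso_nu", "PPG_AUC_ratio", "PPG_PW_25", "PPG_PW_50",
    "PPG_PW_75", "PPG_width_ratio", "PPG_mean_slope_os", "PPG_mean_slope_so",
    "PPG_rise_time", "PPG_decay_time", "PPG_pulse_duration",
    "PPG_sys_time_frac", "PPG_notch_time_frac", "PPG_notch_depth",
    "PPG_notch_to_offset", "PPG_dias_amp_ratio", "PPG_perfusion_index",
    "PPG_pulse_interval")
}

vpg_series_names <- function() {
  c("VPG_max", "VPG_min", "VPG_ratio", "VPG_max_time", "VPG_min_time")
}

apg_series_names <- function() {
  c("APG_a", "APG_b", "APG_b_a_ratio", "APG_a_time", "APG_b_time")
}

coupling_series_names <- function() c("PAT_ms", "PAT_sys_ms", "PTT_notch_ms")

ecg_series_names <- function() {
  paste0("ECG_", c("rr_ms", "hr_bpm", "r_amp", "p_amp", "q_amp", "s_amp",
                   "t_amp", "qrs_duration", "pr_interval", "rt_ratio",
                   "rr_ratio", "st_level", "tpeak_time"))
}

resp_series_names <- function() {
  paste0("RESP_", c("breath_period", "insp_duration", "exp_duration",
                    "ie_ratio", "inst_rate", "breath_amplitude",
                    "breath_width50", "insp_slope", "exp_slope", "asymmetry",
                    "ti_ttot"))
}

edr_series_names <- function() {
  c("EDR_breath_period", "EDR_inst_rate", "EDR_ie_ratio", "EDR_breath_amplitude")
}

#' The physiomarker catalog manifest
#'
#' Enumerates every marker definition the interpreter produces, its domain
#' group (cardiac electrical activity, heart rate variability, PPG
#' morphology/timing, respiratory dynamics, ECG--PPG coupling), value kind
#' (`scalar` vs `series`, the latter expanded by the retained summary
#' statistics), and the channels it requires. The default manifest defines
#' exactly 192 unique physiomarkers.
#'
#' @return data frame with columns `name`, `group`, `kind`, `channels`.
#' @export
physiomarker_catalog <- function() {
  rows <- list(
    # scalar interval-dynamics batteries
    data.frame(name = paste0("HRV_", battery_names(TRUE)), group = "hrv",
               kind = "scalar", channels = "ecg"),
    data.frame(name = paste0("PRV_", battery_names(TRUE)), group = "ppg",
               kind = "scalar", channels = "ppg"),
    data.frame(name = paste0("BRV_", battery_names(FALSE)), group = "respiratory",
               kind = "scalar", channels = "resp"),
    data.frame(name = paste0("PPG_interbeat_eigval", 1:10), group = "ppg",
               kind = "scalar", channels = "ppg"),
    # time-varying series
    data.frame(name = ecg_series_names(), group = "cardiac_electrical",
               kind = "series", channels = "ecg"),
    data.frame(name = edr_series_names(), group = "respiratory",
               kind = "series", channels = "ecg"),
    data.frame(name = ppg_series_names(), group = "ppg",
               kind = "series", channels = "ppg"),
    data.frame(name = vpg_series_names(), group = "ppg",
               kind = "series", channels = "ppg"),
    data.frame(name = apg_series_names(), group = "ppg",
               kind = "series", channels = "ppg"),
    data.frame(name = coupling_series_names(), group = "coupling",
               kind = "series", channels = "ecg+ppg"),
    data.frame(name = resp_series_names(), group = "respiratory",
               kind = "series", channels = "resp")
  )
  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  stopifnot(!anyDuplicated(cat$name))
  cat
}

#' Feature column names implied by the catalog
#'
#' Scalar markers contribute their own name; series markers contribute one
#' column per retained summary statistic (`<marker>_<stat>`).
#'
#' @param catalog output of [physiomarker_catalog()].
#' @return character vector of feature column names.
#' @export
catalog_feature_names <- function(catalog = physiomarker_catalog()) {
  unlist(lapply(seq_len(nrow(catalog)), function(i) {
    if (catalog$kind[i] == "scalar") return(catalog$name[i])
    paste0(catalog$name[i], "_", retained_stats())
  }), use.names = FALSE)
}
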