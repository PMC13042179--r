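# Archetype specifications and cohort configuration for the synthetic
# waveform cohort generator.

#' Construct an archetype specification
#'
#' An archetype bundles the statistical targets of one planted physio-phenotype:
#' heart-rate level, HRV magnitude targets (SDNN, RMSSD, pNN50, LF/HF,
#' skewness, irregularity), PPG pulse morphology, respiratory rate, and the
#' archetype-linked outcome/covariate probabilities. The RR generator is
#' calibrated against these targets in expectation, not exactly.
#'
#' @param id label, e.g. `"SP1"`.
#' @param hr_mean mean heart rate, beats/min; must lie in (20, 250).
#' @param sdnn_target,rmssd_target HRV magnitude targets, ms (non-negative).
#' @param pnn50_target percent of successive differences > 50 ms, in \[0, 100\].
#' @param lfhf_target target low/high-frequency power ratio.
#' @param rr_skew_target target skewness of the RR distribution.
#' @param rr_irregularity `"low"`, `"mid"` or `"high"`; controls how entropic
#'   (white vs. smoothly autocorrelated) the beat-to-beat jitter is.
#' @param ppg_ac_skew_target target skewness of per-beat PPG AC amplitudes.
#' @param ppg_morphology list with `rise_frac` (relative systolic-rise
#'   fraction of the pulse), `notch_prom` (dicrotic notch prominence fraction,
#'   in \[0, 1)), `pat_ms` (pulse-arrival delay from the R peak, ms).
#' @param resp_rate breaths/min.
#' @param mortality_28d probability of death by day 28.
#' @param shock_probs,vp_probs,mv_probs length-3 cumulative probabilities of
#'   septic shock / vasopressor use / mechanical ventilation at days 2, 7, 28
#'   (must be non-decreasing).
#' @param covariate_probs length-3 probabilities of SBP <= 100 mmHg,
#'   RR >= 22 breaths/min, GCS < 15.
#' @return an object of class `archetype_spec`.
#' @export
archetype_spec <- function(id, hr_mean, sdnn_target, rmssd_target, pnn50_target,
                           lfhf_target, rr_skew_target,
                           rr_irregularity = c("mid", "low", "high"),
                           ppg_ac_skew_target = 0,
                           ppg_morphology = list(rise_frac = 0.3, notch_prom = 0.25, pat_ms = 220),
                           resp_rate = 18,
                           mortality_28d = 0.25,
                           shock_probs = c(0.2, 0.25, 0.3),
                           vp_probs = c(0.2, 0.25, 0.3),
                           mv_probs = c(0.2, 0.25, 0.3),
                           covariate_probs = c(0.4, 0.4, 0.4)) {
  rr_irregularity <- match.arg(rr_irregularity)
  stopifnot(is.character(id), length(id) == 1L)
  vals <- c(hr_mean, sdnn_target, rmssd_target, pnn50_target, lfhf_target,
            rr_skew_target, ppg_ac_skew_target, resp_rate, mortality_28d,
            shock_probs, vp_probs, mv_probs, covariate_probs)
  if (!all(is.finite(vals))) stop("archetype targets must be finite")
  if (hr_mean <= 20 || hr_mean >= 250) stop("hr_mean must be in (20, 250)")
  if (sdnn_target < 0 || rmssd_target < 0) stop("sdnn_target and rmssd_target must be >= 0")
  if (pnn50_target < 0 || pnn50_target > 100) stop("pnn50_target must be in [0, 100]")
  probs <- c(mortality_28d, shock_probs, vp_probs, mv_probs, covariate_probs)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  for (p in list(shock_probs, vp_probs, mv_probs)) {
    if (length(p) != 3L || is.unsorted(p)) stop("day-2/7/28 probabilities must be non-decreasing, length 3")
  }
  if (!is.list(ppg_morphology) ||
      !all(c("rise_frac", "notch_prom", "pat_ms") %in% names(ppg_morphology))) {
    stop("ppg_morphology must list rise_frac, notch_prom, pat_ms")
  }
  if (ppg_morphology$notch_prom < 0 || ppg_morphology$notch_prom >= 1) {
    stop("notch prominence must lie in [0, 1)")
  }
  structure(list(
    id = id, hr_mean = hr_mean, sdnn_target = sdnn_target,
    rmssd_target = rmssd_target, pnn50_target = pnn50_target,
    lfhf_target = lfhf_target, rr_skew_target = rr_skew_target,
    rr_irregularity = rr_irregularity, ppg_ac_skew_target = ppg_ac_skew_target,
    ppg_morphology = ppg_morphology, resp_rate = resp_rate,
    mortality_28d = mortality_28d, shock_probs = shock_probs,
    vp_probs = vp_probs, mv_probs = mv_probs, covariate_probs = covariate_probs
  ), class = "archetype_spec")
}

#' Default archetype parameter table
#'
#' Reads the packaged parameter file and returns the four default archetypes
#' (SP1--SP4). HRV and PPG statistical targets are the per-phenotype medians of
#' the reference cohort characteristics table; quantities that table does not
#' print are fixed, once, at clinically plausible values (see the file header
#' and the methods vignette).
#'
#' @return named list of four `archetype_spec` objects.
#' @export
default_archetypes <- function() {
  path <- system.file("extdata", "archetype_params.csv", package = "physiophen")
  if (path == "") path <- file.path("inst", "extdata", "archetype_params.csv")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    archetype_spec(
      id = r$id, hr_mean = r$hr_mean, sdnn_target = r$sdnn_target,
      rmssd_target = r$rmssd_target, pnn50_target = r$pnn50_target,
      lfhf_target = r$lfhf_target, rr_skew_target = r$rr_skew_target,
      rr_irregularity = r$rr_irregularity,
      ppg_ac_skew_target = r$ppg_ac_skew_target,
      ppg_morphology = list(rise_frac = r$ppg_rise_frac,
                            notch_prom = r$ppg_notch_prom,
                            pat_ms = r$ppg_pat_ms),
      resp_rate = r$resp_rate, mortality_28d = r$mortality_28d,
      shock_probs = c(r$shock_d2, r$shock_d7, r$shock_d28),
      vp_probs = c(r$vp_d2, r$vp_d7, r$vp_d28),
      mv_probs = c(r$mv_d2, r$mv_d7, r$mv_d28),
      covariate_probs = c(r$p_sbp_low, r$p_rr_high, r$p_gcs_low)
    )
  })
  names(out) <- tab$id
  out
}

#' Cohort generation configuration
#'
#' @param n_patients number of patients to simulate.
#' @param mixture_weights archetype mixture weights; default are the
#'   phenotype prevalences of the reference cohort (26.7/33.2/27.6/12.5%).
#' @param duration_s waveform segment length, seconds (default 300, the
#'   5-minute region of interest).
#' @param fs named sampling rates, Hz, per channel.
#' @param seed integer seed governing every random draw of the cohort.
#' @param archetypes list of `archetype_spec`; defaults to [default_archetypes()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          mixture_weights = c(0.267, 0.332, 0.276, 0.125),
                          duration_s = 300,
                          fs = c(ecg = 250, ppg = 125, resp = 62.5),
                          seed = 1L,
                          archetypes = default_archetypes()) {
  stopifnot(n_patients >= 0, length(mixture_weights) == length(archetypes))
  if (abs(sum(mixture_weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (any(mixture_weights < 0)) stop("mixture weights must be non-negative")
  min_period <- 60 / max(vapply(archetypes, function(a) a$hr_mean, 0))
  if (duration_s <= 10 * min_period) stop("duration_s too short for the fastest archetype")
  structure(list(n_patients = as.integer(n_patients),
                 mixture_weights = mixture_weights,
                 duration_s = duration_s, fs = fs, seed = as.integer(seed),
                 archetypes = archetypes),
            class = "cohort_config")
}
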