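# Cohort assembly: waveform records, covariates, outcomes, container I/O.

#' Construct a multichannel waveform record
#'
#' @param channels named list; each element a list with `x` (numeric samples),
#'   `fs` (Hz) and optional `units`.
#' @param start_time POSIXct or numeric origin (informational).
#' @return object of class `waveform_record` with an all-`TRUE` quality mask.
#' @export
waveform_record <- function(channels, start_time = 0) {
  stopifnot(is.list(channels), length(channels) >= 1L, !is.null(names(channels)))
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch$x) || !is.numeric(ch$fs) || ch$fs <= 0) {
      stop("each channel needs numeric samples and fs > 0")
    }
    channels[[nm]]$units <- ch$units %||% "au"
  }
  structure(list(
    channels = channels,
    start_time = start_time,
    quality = lapply(channels, function(ch) rep(TRUE, length(ch$x)))
  ), class = "waveform_record")
}

# First-activation day for a monotone day-2/7/28 exposure flag.
# Returns Inf (never), 2, 7 or 28 given cumulative probabilities.
sample_activation_day <- function(p) {
  u <- stats::runif(1)
  if (u < p[1]) 2 else if (u < p[2]) 7 else if (u < p[3]) 28 else Inf
}

# Patient-level biological heterogeneity: archetype targets are jittered per
# patient (multiplicative lognormal for rates/magnitudes, additive for
# delays) so that within-phenotype physiology is a continuum around the
# archetype signature rather than identical replicas.
jitter_archetype <- function(arch, seed) {
  with_seed(seed, {
    lg <- function(sd) exp(stats::rnorm(1, 0, sd))
    arch$hr_mean <- min(240, max(25, arch$hr_mean * lg(0.05)))
    arch$sdnn_target <- arch$sdnn_target * lg(0.15)
    arch$rmssd_target <- arch$rmssd_target * lg(0.15)
    arch$pnn50_target <- min(95, arch$pnn50_target * lg(0.15))
    arch$lfhf_target <- arch$lfhf_target * lg(0.15)
    arch$resp_rate <- min(45, max(8, arch$resp_rate * lg(0.08)))
    m <- arch$ppg_morphology
    m$rise_frac <- min(0.45, max(0.18, m$rise_frac * lg(0.08)))
    m$notch_prom <- min(0.85, max(0, m$notch_prom * lg(0.15)))
    m$pat_ms <- max(120, m$pat_ms + stats::rnorm(1, 0, 10))
    arch$ppg_morphology <- m
    arch$ppg_ac_skew_target <- arch$ppg_ac_skew_target + stats::rnorm(1, 0, 0.1)
    arch
  })
}

# Generate one patient (waveforms + covariates + outcome), reproducible from
# (cohort seed, patient index, archetype). Waveform synthesis can be skipped
# (covariates/outcomes draw from independent seed streams, so metadata is
# identical either way).
generate_patient <- function(arch, config, patient_idx, make_waveforms = TRUE) {
  seed_p <- derive_seed(config$seed, patient_idx)
  rec <- NULL
  rr <- NULL
  if (make_waveforms) {
  arch <- jitter_archetype(arch, derive_seed(seed_p, 6L))
  rr <- generate_rr_series(arch, config$duration_s, derive_seed(seed_p, 1L))
  resp <- synthesize_resp(arch$resp_rate, config$fs[["resp"]], config$duration_s,
                          seed = derive_seed(seed_p, 2L))
  # respiratory phase resampled onto the ECG grid drives R-amplitude modulation
  n_ecg <- floor((sum(rr) / 1000 + 0.5) * config$fs[["ecg"]])
  t_ecg <- (seq_len(n_ecg) - 1L) / config$fs[["ecg"]]
  t_resp <- (seq_along(resp$x) - 1L) / resp$fs
  rp <- stats::approx(t_resp, resp$x, xout = t_ecg, rule = 2)$y
  ecg <- synthesize_ecg(rr, config$fs[["ecg"]], resp_phase = rp,
                        seed = derive_seed(seed_p, 3L))
  ppg <- synthesize_ppg(rr, arch$ppg_morphology, config$fs[["ppg"]],
                        seed = derive_seed(seed_p, 4L),
                        ac_skew_target = arch$ppg_ac_skew_target)
  rec <- waveform_record(list(ecg = ecg, ppg = ppg, resp = resp))
  }

  cov_out <- with_seed(derive_seed(seed_p, 5L), {
    ab <- stats::runif(3) < arch$covariate_probs
    sbp <- if (ab[1]) stats::runif(1, 70, 100) else stats::runif(1, 101, 145)
    rrate <- if (ab[2]) stats::runif(1, 22, 35) else stats::runif(1, 12, 21.5)
    gcs <- if (ab[3]) sample(3:14, 1, prob = (3:14)^2) else 15L
    lam <- -log(1 - min(arch$mortality_28d, 0.999)) / 28
    if (lam > 0) {
      td <- stats::rexp(1, rate = lam)
    } else td <- Inf
    event <- td <= 28
    list(sbp = sbp, rr = rrate, gcs = as.integer(gcs),
         death_time = if (event) max(td, 1e-3) else 28, death_event = event,
         shock_day = sample_activation_day(arch$shock_probs),
         vp_day = sample_activation_day(arch$vp_probs),
         mv_day = sample_activation_day(arch$mv_probs))
  })
  list(record = rec, rr_truth = rr, covariates = cov_out)
}

#' Generate a synthetic sepsis waveform cohort
#'
#' Draws an archetype per patient from the mixture, simulates the three
#' waveform channels, qSOFA-style covariates (SBP, respiratory rate, GCS) and
#' outcomes (28-day death/censoring; monotone septic-shock / vasopressor /
#' ventilation flags at days 2/7/28). Deterministic under `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param keep_waveforms if `FALSE`, only metadata and ground truth are kept
#'   (waveforms can be regenerated per patient from the seed).
#' @return object of class `synthetic_cohort`: `metadata` data frame (one row
#'   per patient, with hidden ground-truth archetype), `patients` (list of
#'   waveform records, or `NULL`), and the `config`.
#' @export
generate_cohort <- function(config, keep_waveforms = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  arch_names <- names(config$archetypes)
  if (n == 0L) {
    meta <- data.frame(patient_id = character(0), archetype = character(0))
    return(structure(list(metadata = meta, patients = list(), config = config),
                     class = "synthetic_cohort"))
  }
  assign_idx <- with_seed(derive_seed(config$seed, 999983L), {
    sample.int(length(arch_names), n, replace = TRUE, prob = config$mixture_weights)
  })
  patients <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    arch <- config$archetypes[[assign_idx[i]]]
    p <- generate_patient(arch, config, i, make_waveforms = keep_waveforms)
    cv <- p$covariates
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%04d", i),
      archetype = arch$id,
      sbp = cv$sbp, resp_rate = cv$rr, gcs = cv$gcs,
      death_time = cv$death_time, death_event = cv$death_event,
      ss2 = cv$shock_day <= 2, ss7 = cv$shock_day <= 7, ss28 = cv$shock_day <= 28,
      vp2 = cv$vp_day <= 2, vp7 = cv$vp_day <= 7, vp28 = cv$vp_day <= 28,
      mv2 = cv$mv_day <= 2, mv7 = cv$mv_day <= 7, mv28 = cv$mv_day <= 28,
      stringsAsFactors = FALSE
    )
    if (keep_waveforms) patients[[i]] <- p$record
  }
  meta <- do.call(rbind, rows)
  # death flags at the three horizons (same monotone convention)
  meta$death2 <- meta$death_event & meta$death_time <= 2
  meta$death7 <- meta$death_event & meta$death_time <= 7
  meta$death28 <- meta$death_event & meta$death_time <= 28
  structure(list(metadata = meta,
                 patients = if (keep_waveforms) patients else NULL,
                 config = config),
            class = "synthetic_cohort")
}

# Regenerate patient i's waveform record from the cohort config (streaming
# extraction without holding all waveforms in memory).
cohort_patient_record <- function(cohort, i) {
  if (!is.null(cohort$patients) && !is.null(cohort$patients[[i]])) {
    return(cohort$patients[[i]])
  }
  arch <- cohort$config$archetypes[[cohort$metadata$archetype[i]]]
  generate_patient(arch, cohort$config, i)$record
}

#' Write a cohort to a plain-text container directory
#'
#' One CSV per patient per channel plus a JSON sidecar carrying sampling
#' rates and units; metadata (covariates, outcomes, ground truth) as CSV.
#'
#' @param cohort a `synthetic_cohort` with waveforms kept.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"), !is.null(cohort$patients))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  for (i in seq_along(cohort$patients)) {
    rec <- cohort$patients[[i]]
    pid <- cohort$metadata$patient_id[i]
    sidecar <- lapply(rec$channels, function(ch) list(fs = ch$fs, units = ch$units))
    jsonlite::write_json(sidecar, file.path(dir, paste0(pid, ".json")),
                         auto_unbox = TRUE)
    for (nm in names(rec$channels)) {
      utils::write.csv(data.frame(x = rec$channels[[nm]]$x),
                       file.path(dir, paste0(pid, "_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a cohort container directory written by [write_cohort()]
#'
#' @param dir container directory.
#' @return a `synthetic_cohort`-like list with `metadata` and `patients`.
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  patients <- lapply(meta$patient_id, function(pid) {
    sidecar <- jsonlite::read_json(file.path(dir, paste0(pid, ".json")))
    chans <- lapply(names(sidecar), function(nm) {
      x <- utils::read.csv(file.path(dir, paste0(pid, "_", nm, ".csv")))$x
      list(x = x, fs = sidecar[[nm]]$fs, units = sidecar[[nm]]$units)
    })
    names(chans) <- names(sidecar)
    waveform_record(chans)
  })
  structure(list(metadata = meta, patients = patients, config = NULL),
            class = "synthetic_cohort")
}
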