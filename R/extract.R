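# Stage 1-6 driver: one waveform record -> one named physiomarker feature row.

#' Extract the full physiomarker feature row from a waveform record
#'
#' Runs the six interpreter stages (quality control, denoising, signal
#' derivation, delineation, marker extraction, summarization) and emits one
#' named feature row: scalar markers as-is, time-varying markers expanded by
#' the five retained summary statistics. Markers whose channels are missing
#' or low-quality are reported as `NA` rather than raising errors.
#'
#' @param record a [waveform_record()].
#' @param qc_rules QC settings forwarded to [preprocess()].
#' @param min_beats minimum detected beats for beat-dependent markers.
#' @return list with `features` (named numeric vector over
#'   [catalog_feature_names()]), `catalog`, `quality` (the QC report), and
#'   `fiducials`.
#' @export
extract_features <- function(record, qc_rules = list(), min_beats = 10L) {
  catalog <- physiomarker_catalog()
  feat_names <- catalog_feature_names(catalog)
  features <- stats::setNames(rep(NA_real_, length(feat_names)), feat_names)

  pp <- preprocess(record, qc_rules)
  rec <- pp$record
  report <- pp$report
  for (nm in names(rec$channels)) {
    if (isTRUE(report[[nm]]$low_quality)) rec$channels[[nm]] <- NULL
  }
  if (!length(rec$channels)) {
    return(list(features = features, catalog = catalog, quality = report,
                fiducials = NULL))
  }
  rec <- denoise(rec)

  has_ecg <- !is.null(rec$channels$ecg)
  fid <- delineate(rec)
  rpeaks <- fid$ecg$r %||% integer(0)
  derived <- derive_signals(rec, rpeaks)

  put_scalar <- function(vals) {
    keep <- intersect(names(vals), names(features))
    features[keep] <<- vals[keep]
  }
  put_series <- function(series_list) {
    for (nm in names(series_list)) {
      cols <- paste0(nm, "_", retained_stats())
      if (!all(cols %in% names(features))) next
      v <- series_list[[nm]]
      if (length(v[is.finite(v)]) >= 2L) {
        features[cols] <<- summarize_retained(v)
      }
    }
  }

  if (has_ecg && length(rpeaks) >= min_beats) {
    rr <- diff(rpeaks) / rec$channels$ecg$fs * 1000
    hrv <- compute_hrv(rr)
    names(hrv) <- paste0("HRV_", names(hrv))
    put_scalar(hrv)
    put_series(compute_ecg_beat_series(rec, rpeaks))
    put_series(compute_edr_markers(derived$edr))
  }

  if (!is.null(rec$channels$ppg)) {
    ppg_m <- compute_ppg_markers(rec, fid, rpeaks, derived)
    put_series(ppg_m$series)
    if (any(is.finite(ppg_m$eig))) {
      eig <- ppg_m$eig
      names(eig) <- paste0("PPG_interbeat_", names(eig))
      put_scalar(eig)
    }
    pi_ms <- filter_nn(ppg_m$pulse_intervals_ms)
    if (length(pi_ms) >= 10L) {
      prv <- interval_battery(pi_ms, spectral = TRUE)
      names(prv) <- paste0("PRV_", names(prv))
      put_scalar(prv)
    }
  }

  if (!is.null(rec$channels$resp)) {
    resp_m <- compute_resp_markers(rec, fid)
    put_series(resp_m)
    bp <- resp_m$RESP_breath_period
    bp <- bp[is.finite(bp)] * 1000  # seconds -> ms for the battery
    if (length(bp) >= 10L) {
      brv <- interval_battery(bp, spectral = FALSE)
      names(brv) <- paste0("BRV_", names(brv))
      put_scalar(brv)
    }
  }

  list(features = features, catalog = catalog, quality = report, fiducials = fid)
}

#' Extract feature rows for a whole cohort
#'
#' Streams patients (regenerating waveforms from the cohort seed when they
#' were not kept in memory) and stacks one feature row per patient.
#'
#' @param cohort a `synthetic_cohort`.
#' @param verbose print progress every 50 patients.
#' @return data frame: `patient_id` plus one column per catalog feature.
#' @export
extract_cohort_features <- function(cohort, verbose = FALSE) {
  n <- nrow(cohort$metadata)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- cohort_patient_record(cohort, i)
    rows[[i]] <- extract_features(rec)$features
    if (verbose && i %% 50L == 0L) message("extracted ", i, "/", n)
  }
  mat <- do.call(rbind, rows)
  out <- data.frame(patient_id = cohort$metadata$patient_id, mat,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
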