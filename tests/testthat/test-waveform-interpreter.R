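# Waveform interpreter: QC, denoising, derivation, delineation, markers.

test_that("flatline, clipping and resampling behave as specified", {
  # constant channel -> fully flat, zero usable
  rec <- waveform_record(list(ecg = list(x = rep(1, 2500), fs = 250)))
  rep1 <- preprocess(rec)$report$ecg
  expect_equal(rep1$flatline_fraction, 1)
  expect_equal(rep1$usable_fraction, 0)
  expect_true(rep1$low_quality)

  # one 2 s rail-clamped run in a 300 s signal
  withr::with_seed(1, x <- sin(2 * pi * (0:(300 * 250 - 1)) / 250) + rnorm(300 * 250, 0, .05))
  x[10000:10499] <- max(x)
  rec2 <- waveform_record(list(ecg = list(x = x, fs = 250)))
  rep2 <- preprocess(rec2)$report$ecg
  expect_equal(rep2$clipping_fraction, 500 / 75000, tolerance = 0.3)
  expect_lte(rep2$usable_fraction, 1 - rep2$flatline_fraction)

  # 300 s at 250 Hz resampled to 125 Hz -> exactly 37500 samples
  rec3 <- waveform_record(list(ecg = list(x = x, fs = 250)))
  out3 <- preprocess(rec3, rules = list(target_fs = c(ecg = 125)))
  expect_length(out3$record$channels$ecg$x, 37500L)
  expect_equal(out3$record$channels$ecg$fs, 125)
})

test_that("outlier samples are masked and interpolated", {
  withr::with_seed(2, x <- rnorm(5000))
  x[1234] <- 40
  rec <- waveform_record(list(resp = list(x = x, fs = 62.5)))
  out <- preprocess(rec)
  expect_gt(out$report$resp$outlier_fraction, 0)
  expect_lt(abs(out$record$channels$resp$x[1234]), 5)
})

test_that("band-pass attenuates out-of-band tones >= 20 dB, keeps in-band within 3 dB", {
  fs <- 250
  t <- (0:(30 * fs - 1)) / fs
  # coherent demodulation: exact tone amplitude, immune to spectral leakage
  tone_power <- function(x, f) {
    tt <- (seq_along(x) - 1) / fs
    (2 * Mod(mean(x * exp(-2i * pi * f * tt))))^2
  }
  base <- sin(2 * pi * 10 * t)
  with60 <- base + sin(2 * pi * 60 * t)
  rec <- waveform_record(list(ecg = list(x = with60, fs = fs)))
  den <- denoise(rec)$channels$ecg$x
  expect_gt(10 * log10(tone_power(with60, 60) / tone_power(den, 60)), 20)
  # in-band 10 Hz within 3 dB
  expect_lt(abs(10 * log10(tone_power(den, 10) / tone_power(base, 10))), 3)

  # 0.05 Hz drift on PPG removed >= 20 dB
  fs2 <- 125
  t2 <- (0:(120 * fs2 - 1)) / fs2
  drift <- sin(2 * pi * 0.05 * t2)
  sig <- sin(2 * pi * 1.2 * t2) + drift
  rec2 <- waveform_record(list(ppg = list(x = sig, fs = fs2)))
  den2 <- denoise(rec2)$channels$ppg$x
  p_before <- tone_power_low <- mean(stats::spec.pgram(stats::ts(sig, frequency = fs2),
                                                       plot = FALSE, taper = 0)$spec[1:8])
  p_after <- mean(stats::spec.pgram(stats::ts(den2, frequency = fs2),
                                    plot = FALSE, taper = 0)$spec[1:8])
  expect_gt(10 * log10(p_before / p_after), 20)
})

test_that("VPG/APG match analytic derivatives of a sinusoid within 1%", {
  fs <- 125
  f0 <- 1.5
  t <- (0:(20 * fs - 1)) / fs
  rec <- waveform_record(list(ppg = list(x = sin(2 * pi * f0 * t), fs = fs)))
  der <- derive_signals(rec, integer(0))
  core <- 200:(length(t) - 200)
  vpg_true <- 2 * pi * f0 * cos(2 * pi * f0 * t)
  apg_true <- -(2 * pi * f0)^2 * sin(2 * pi * f0 * t)
  expect_lt(max(abs(der$vpg$x[core] - vpg_true[core])) / max(abs(vpg_true)), 0.01)
  expect_lt(max(abs(der$apg$x[core] - apg_true[core])) / max(abs(apg_true)), 0.03)
})

test_that("EDR is constant when R amplitudes are constant", {
  ecg <- synthesize_ecg(rep(1000, 30), 250, seed = 1, r_mod_depth = 0,
                        snr_db = Inf, wander_amp = 0)
  rec <- waveform_record(list(ecg = ecg))
  r <- physiophen:::detect_rpeaks(ecg$x, 250)
  der <- derive_signals(rec, r)
  expect_lt(stats::sd(der$edr$x), 1e-3 * mean(abs(der$edr$x)))
})

test_that("R peaks on clean synthetic ECG land within 10 ms of truth", {
  rr <- rep(c(900, 1000, 1100), 20)
  ecg <- synthesize_ecg(rr, 250, seed = 3, snr_db = Inf, wander_amp = 0,
                        r_mod_depth = 0)
  truth <- attr(ecg, "beat_times_s")
  rec <- denoise(waveform_record(list(ecg = ecg)))
  r <- delineate(rec)$ecg$r
  expect_equal(length(r), length(truth))
  err_ms <- abs((r - 1) / 250 - truth) * 1000
  expect_lt(max(err_ms), 10)
})

test_that("respiratory delineation counts inspiration onsets exactly", {
  r <- synthesize_resp(15, 62.5, 60, seed = 1, jitter = 0)
  fid <- physiophen:::delineate_resp(r$x, 62.5)
  expect_equal(length(fid$up), 15L)
})

test_that("HRV formulas match brute-force oracles to 1e-9", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      nn <- runif(120, 600, 1100)
      h <- compute_hrv(nn, nn_filter = FALSE)
      d <- diff(nn)
      expect_equal(unname(h["SDNN"]), sd(nn), tolerance = 1e-9)
      expect_equal(unname(h["RMSSD"]), sqrt(mean(d^2)), tolerance = 1e-9)
      expect_equal(unname(h["pNN50"]), 100 * mean(abs(d) > 50), tolerance = 1e-9)
      expect_equal(unname(h["MinNN"]), min(nn), tolerance = 1e-9)
      expect_equal(unname(h["MaxNN"]), max(nn), tolerance = 1e-9)
    }
  })
})

test_that("worked HRV example: alternating 800/860 ms", {
  nn <- rep(c(800, 860), 30)
  h <- compute_hrv(nn, nn_filter = FALSE)
  expect_equal(unname(h["RMSSD"]), 60, tolerance = 1e-9)
  expect_equal(unname(h["pNN50"]), 100, tolerance = 1e-9)
  expect_equal(unname(h["SDNN"]), sd(nn), tolerance = 1e-9)  # 30.25 ms
  expect_equal(round(unname(h["SDNN"]), 2), 30.25)
})

test_that("constant NN series degenerates correctly", {
  h <- compute_hrv(rep(1000, 60), nn_filter = FALSE)
  expect_equal(unname(h["SDNN"]), 0)
  expect_equal(unname(h["RMSSD"]), 0)
  expect_equal(unname(h["pNN50"]), 0)
  expect_equal(unname(h["KFD"]), 1)
})

test_that("sample entropy separates white noise from a sinusoid of equal SD", {
  withr::with_seed(3, {
    n <- 300
    wins <- 0
    for (rep in 1:5) {
      white <- rnorm(n)
      sine <- sqrt(2) * sin(2 * pi * (1:n) / 25)
      se_w <- sample_entropy(white, 2, 0.2 * sd(white))
      se_s <- sample_entropy(sine, 2, 0.2 * sd(sine))
      wins <- wins + (se_w > se_s)
    }
    expect_gte(wins, 4)
  })
})

test_that("sample entropy agrees with a naive O(n^2) oracle implementation", {
  naive_sampen <- function(x, m, r) {
    N <- length(x) - m
    cnt <- function(mm) {
      tot <- 0L
      for (i in 1:(N - 1)) for (j in (i + 1):N) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) tot <- tot + 1L
      }
      tot
    }
    -log(cnt(m + 1) / cnt(m))
  }
  withr::with_seed(9, x <- rnorm(60))
  r <- 0.25 * sd(x)
  expect_equal(sample_entropy(x, 2, r), naive_sampen(x, 2, r), tolerance = 1e-12)
})

test_that("NN filtering removes out-of-range and abrupt-change intervals", {
  rr <- c(800, 810, 2500, 805, 250, 795, 1300, 790)
  nn <- filter_nn(rr)
  expect_false(any(nn > 2000 | nn < 300))
  expect_true(all(abs(diff(nn)) / nn[-length(nn)] <= 0.3))
})

test_that("PPG marker geometry on a symmetric triangular pulse", {
  fs <- 1000
  half <- 250
  x <- c(seq(0, 1, length.out = half + 1), seq(1, 0, length.out = half + 1)[-1])
  n <- length(x)
  rec <- waveform_record(list(ppg = list(x = x, fs = fs)))
  fid <- list(ppg = data.frame(onset = 1L, sys = half + 1L, notch = NA_integer_,
                               dias = NA_integer_, offset = n))
  derived <- list(vpg = list(x = c(0, diff(x)) * fs, fs = fs),
                  apg = list(x = c(0, 0, diff(diff(x))) * fs^2, fs = fs))
  # bypass the minimum-pulse-count guard by repeating the same pulse
  fid$ppg <- fid$ppg[rep(1, 6), ]
  m <- compute_ppg_markers(rec, fid, derived = derived)
  pw50 <- m$series$PPG_PW_50[1]
  dur <- m$series$PPG_pulse_duration[1]
  expect_equal(pw50 / dur, 0.5, tolerance = 0.01)
  expect_equal(m$series$PPG_AUCos_nu[1], 0.25, tolerance = 0.01)
  expect_equal(m$series$PPG_AUCso_nu[1], 0.25, tolerance = 0.01)
  # identical pulses -> zero covariance spectrum
  expect_equal(unname(m$eig["eigval1"]), 0, tolerance = 1e-12)
})

test_that("pulse widths nest (PW75 <= PW50 <= PW25) and PPG markers obey shift/scale contracts", {
  fx <- clean_record(11)
  rec <- denoise(physiophen:::preprocess(fx$record)$record)
  fid <- delineate(rec)
  m <- compute_ppg_markers(rec, fid)
  ok <- stats::complete.cases(cbind(m$series$PPG_PW_25, m$series$PPG_PW_50,
                                    m$series$PPG_PW_75))
  expect_gt(sum(ok), 10)
  expect_true(all(m$series$PPG_PW_75[ok] <= m$series$PPG_PW_50[ok] + 1e-9))
  expect_true(all(m$series$PPG_PW_50[ok] <= m$series$PPG_PW_25[ok] + 1e-9))

  # shift: A_AC, PW, normalized AUCs unchanged; scale: A_AC scales, rest fixed
  shift_scale <- function(a, b) {
    r2 <- rec
    r2$channels$ppg$x <- a * rec$channels$ppg$x + b
    compute_ppg_markers(r2, fid)
  }
  m_shift <- shift_scale(1, 5)
  m_scale <- shift_scale(3, 0)
  for (nm in c("PPG_A_AC", "PPG_PW_50", "PPG_AUCos_nu", "PPG_AUCso_nu")) {
    expect_equal(m_shift$series[[nm]], m$series[[nm]], tolerance = 1e-9)
  }
  expect_equal(m_scale$series$PPG_A_AC, 3 * m$series$PPG_A_AC, tolerance = 1e-9)
  expect_equal(m_scale$series$PPG_AUCos_nu, m$series$PPG_AUCos_nu, tolerance = 1e-9)
  expect_equal(m_scale$series$PPG_PW_50, m$series$PPG_PW_50, tolerance = 1e-9)
})

test_that("planted pulse-arrival time is recovered", {
  fx <- clean_record(11)
  rec <- denoise(physiophen:::preprocess(fx$record)$record)
  fid <- delineate(rec)
  m <- compute_ppg_markers(rec, fid, rpeaks = fid$ecg$r)
  pat <- m$series$PAT_ms
  expect_gt(sum(is.finite(pat)), 20)
  # one PPG sample at 125 Hz = 8 ms; allow detection quantization on top
  expect_lt(abs(stats::median(pat, na.rm = TRUE) - fx$arch$ppg_morphology$pat_ms), 17)
})

test_that("respiratory cycle markers reproduce planted timing", {
  r <- synthesize_resp(15, 62.5, 120, seed = 1, jitter = 0)
  rec <- waveform_record(list(resp = list(x = r$x, fs = 62.5)))
  fid <- delineate(rec)
  m <- compute_resp_markers(rec, fid)
  expect_equal(mean(m$RESP_inst_rate, na.rm = TRUE), 15, tolerance = 0.05)
  expect_equal(stats::median(m$RESP_ie_ratio, na.rm = TRUE), 1, tolerance = 0.05)

  # sawtooth: 1 s rise, 3 s fall -> I:E = 1/3
  fs <- 62.5
  cyc <- c(seq(-1, 1, length.out = fs * 1), seq(1, -1, length.out = fs * 3))
  x <- rep(cyc, 20)
  rec2 <- waveform_record(list(resp = list(x = x, fs = fs)))
  m2 <- compute_resp_markers(rec2, delineate(rec2))
  expect_equal(stats::median(m2$RESP_ie_ratio, na.rm = TRUE), 1 / 3,
               tolerance = 0.05)
})

test_that("summary statistics behave on worked examples", {
  s <- summarize_series(rep(5, 20))
  expect_equal(unname(s[c("sd", "mad", "iqr", "gini", "entropy")]),
               rep(0, 5))
  s2 <- summarize_series(c(1, 2, 3, 4))
  expect_equal(unname(s2["mean"]), 2.5)
  expect_equal(unname(s2["min"]), 1)
  expect_equal(unname(s2["max"]), 4)
  expect_equal(unname(s2["slope"]), 1)
  s3 <- summarize_series(rep(c(1, -1), 20))
  expect_equal(unname(s3["lag1_autocorr"]), -1, tolerance = 1e-12)
  expect_true(all(is.na(summarize_series(c(NA, NA, 3))[c("mean", "sd")])))
  expect_identical(retained_stats(), c("mean", "p25", "p75", "skewness", "entropy"))
})

test_that("the physiomarker catalog defines exactly 192 unique markers", {
  cat <- physiomarker_catalog()
  expect_equal(nrow(cat), 192L)
  expect_false(anyDuplicated(cat$name) > 0)
  expect_setequal(unique(cat$group),
                  c("hrv", "ppg", "respiratory", "cardiac_electrical", "coupling"))
  expect_true(all(cat$kind %in% c("scalar", "series")))
})

test_that("a clean archetype record yields a complete feature row", {
  fx <- clean_record(11)
  ex <- extract_features(fx$record)
  expect_equal(sum(is.na(ex$features)), 0L)
  expect_length(ex$features, length(catalog_feature_names()))
})

test_that("removing the PPG channel blanks PPG-derived columns only", {
  fx <- clean_record(11)
  rec <- fx$record
  rec$channels$ppg <- NULL
  rec$quality$ppg <- NULL
  ex <- extract_features(rec)
  cat <- physiomarker_catalog()
  ppg_cols <- catalog_feature_names(cat[grepl("ppg", cat$channels), ])
  other_cols <- setdiff(catalog_feature_names(cat), ppg_cols)
  expect_true(all(is.na(ex$features[ppg_cols])))
  expect_lt(mean(is.na(ex$features[other_cols])), 0.05)
})

test_that("a low-quality record produces missing markers, not an error", {
  rec <- waveform_record(list(ecg = list(x = rep(0, 30000), fs = 250)))
  ex <- extract_features(rec)
  expect_true(all(is.na(ex$features)))
})
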