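# Synthetic cohort generator: RR model, channel synthesizers, cohort bundle.

test_that("degenerate archetype yields a constant RR series", {
  z <- archetype_spec("Z", hr_mean = 60, sdnn_target = 0, rmssd_target = 0,
                      pnn50_target = 0, lfhf_target = 1, rr_skew_target = 0)
  rr <- generate_rr_series(z, 60, seed = 1)
  expect_true(all(rr == 1000))
  expect_equal(stats::sd(rr), 0)
  expect_equal(mean(abs(diff(rr)) > 50), 0)
})

test_that("RR generation is deterministic under seed and covers the horizon", {
  arch <- default_archetypes()$SP3
  rr1 <- generate_rr_series(arch, 300, seed = 42)
  rr2 <- generate_rr_series(arch, 300, seed = 42)
  expect_identical(rr1, rr2)
  rr3 <- generate_rr_series(arch, 300, seed = 43)
  expect_false(identical(rr1, rr3))
  expect_gte(sum(rr1), 300 * 1000)
  expect_true(all(rr1 > 200))
})

test_that("SP-1 SDNN target is recovered by the HRV extractor within 25%", {
  arch <- default_archetypes()$SP1
  sdnn <- vapply(1:10, function(s) {
    rr <- generate_rr_series(arch, 300, seed = s)
    unname(compute_hrv(rr)["SDNN"])
  }, 0)
  expect_lt(abs(stats::median(sdnn) - 9.28) / 9.28, 0.25)
})

test_that("archetype signatures are ordered as planted (cohort medians)", {
  a <- default_archetypes()
  med <- sapply(names(a), function(id) {
    vals <- sapply(1:7, function(s) {
      hrv <- compute_hrv(generate_rr_series(a[[id]], 300, seed = s))
      hrv[c("SDNN", "pNN50")]
    })
    rowMeans(vals)
  })
  expect_gt(med["SDNN", "SP3"], med["SDNN", "SP2"])
  expect_gt(med["SDNN", "SP2"], med["SDNN", "SP1"])
  expect_true(all(med["pNN50", "SP4"] > med["pNN50", c("SP1", "SP2", "SP3")]))
})

test_that("clean ECG synthesis places one R peak per beat at the beat times", {
  ecg <- synthesize_ecg(rep(1000, 10), 250, seed = 1, r_mod_depth = 0,
                        snr_db = Inf, wander_amp = 0)
  x <- ecg$x
  pk <- which(diff(sign(diff(x))) == -2) + 1L
  pk <- pk[x[pk] > 0.5 * max(x)]
  expect_length(pk, 10L)
  gaps_ms <- diff(pk) / 250 * 1000
  expect_true(all(abs(gaps_ms - 1000) <= 4))
})

test_that("zero modulation depth gives constant per-beat R amplitudes", {
  ecg <- synthesize_ecg(rep(900, 12), 250, seed = 2, r_mod_depth = 0,
                        snr_db = Inf, wander_amp = 0)
  amps <- attr(ecg, "r_amps")
  expect_equal(max(amps) - min(amps), 0)
})

test_that("R-peak detection jitter grows as ECG SNR decreases", {
  rr <- rep(800, 60)
  truth <- cumsum(rr) / 1000
  jit <- vapply(c(30, 10, 0), function(snr) {
    med <- stats::median(vapply(1:3, function(s) {
      ecg <- synthesize_ecg(rr, 250, seed = s, snr_db = snr, wander_amp = 0)
      r <- physiophen:::detect_rpeaks(ecg$x, 250)
      t_det <- (r - 1) / 250
      mean(vapply(truth, function(tt) min(abs(t_det - tt)), 0)) * 1000
    }, 0))
    med
  }, 0)
  expect_true(all(diff(jit) >= 0))
})

test_that("ECG synthesis rejects sampling rates below the QRS Nyquist need", {
  expect_error(synthesize_ecg(rep(1000, 5), 50, seed = 1), "Nyquist")
})

test_that("PPG produces one pulse per beat and honors the notch setting", {
  rr <- rep(1000, 20)
  m <- list(rise_frac = 0.3, notch_prom = 0.3, pat_ms = 200)
  ppg <- synthesize_ppg(rr, m, 125, seed = 1, snr_db = Inf)
  rec <- waveform_record(list(ppg = ppg))
  rec <- denoise(rec)
  fid <- delineate(rec)
  expect_gte(nrow(fid$ppg), length(rr) - 3L)
  expect_gt(mean(!is.na(fid$ppg$notch)), 0.8)

  m0 <- list(rise_frac = 0.3, notch_prom = 0, pat_ms = 200)
  ppg0 <- synthesize_ppg(rr, m0, 125, seed = 1, snr_db = Inf)
  rec0 <- denoise(waveform_record(list(ppg = ppg0)))
  fid0 <- delineate(rec0)
  expect_true(all(is.na(fid0$ppg$notch)))
  expect_true(all(!is.na(fid0$ppg$sys)))
  expect_error(synthesize_ppg(rr, list(rise_frac = 0.3, notch_prom = 1.2,
                                       pat_ms = 200), 125), "notch")
})

test_that("symmetric PPG amplitude distribution has near-zero sample skewness", {
  rr <- rep(600, 500)
  sk <- vapply(1:5, function(s) {
    ppg <- synthesize_ppg(rr, list(rise_frac = 0.3, notch_prom = 0.2, pat_ms = 200),
                          125, seed = s, ac_skew_target = 0)
    sample_skewness(attr(ppg, "ac_amps"))
  }, 0)
  expect_lt(abs(stats::median(sk)), 0.2)
})

test_that("respiration synthesis produces the requested cycle count and spectrum", {
  r <- synthesize_resp(15, 62.5, 60, seed = 1, jitter = 0)
  xm <- r$x - mean(r$x)
  up <- sum(diff(sign(xm)) > 0)
  expect_equal(up, 15L)
  sp <- stats::spec.pgram(stats::ts(r$x, frequency = 62.5), plot = FALSE,
                          taper = 0, detrend = TRUE)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 0.25), 0.02)
  expect_equal(stats::sd(diff(which(diff(sign(xm)) > 0))), 0)  # equal cycles
  expect_error(synthesize_resp(2, 62.5, 60), "resp_rate")
})

test_that("cohort bundle respects mixture weights, outcomes, determinism", {
  cc <- cohort_config(400, seed = 9)
  co <- generate_cohort(cc, keep_waveforms = FALSE)
  counts <- table(factor(co$metadata$archetype, c("SP1", "SP2", "SP3", "SP4")))
  w <- c(0.267, 0.332, 0.276, 0.125)
  for (i in 1:4) {
    expect_lt(abs(counts[i] - 400 * w[i]), 3 * sqrt(400 * w[i] * (1 - w[i])) + 1)
  }
  m <- co$metadata
  expect_true(all(m$death_time > 0 & m$death_time <= 28))
  expect_true(all(!m$ss2 | m$ss7))
  expect_true(all(!m$ss7 | m$ss28))
  expect_true(all(!m$vp2 | m$vp7), all(!m$mv7 | m$mv28))
  co2 <- generate_cohort(cc, keep_waveforms = FALSE)
  expect_identical(co$metadata, co2$metadata)
  # zero mortality -> everyone censored at the horizon
  arch0 <- lapply(default_archetypes(), function(a) { a$mortality_28d <- 0; a })
  cc0 <- cohort_config(30, seed = 2, archetypes = arch0)
  co0 <- generate_cohort(cc0, keep_waveforms = FALSE)
  expect_true(all(!co0$metadata$death_event))
  expect_true(all(co0$metadata$death_time == 28))
  # empty bundle
  co_empty <- generate_cohort(cohort_config(0, seed = 1))
  expect_equal(nrow(co_empty$metadata), 0L)
})

test_that("cohort container round-trips through the plain-text format", {
  cc <- cohort_config(2, seed = 4, duration_s = 70)
  co <- generate_cohort(cc)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$metadata$archetype, co$metadata$archetype)
  expect_equal(back$patients[[1]]$channels$ecg$fs, 250)
  expect_equal(back$patients[[1]]$channels$ecg$x,
               co$patients[[1]]$channels$ecg$x, tolerance = 1e-6)
})
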