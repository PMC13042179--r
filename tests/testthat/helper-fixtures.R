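# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A clean (noise-free, archetype SP2) waveform record plus its generator
# ground truth.
clean_record <- function(seed = 11L, duration_s = 120) {
  cached(paste0("rec", seed, "_", duration_s), {
    arch <- default_archetypes()$SP2
    rr <- generate_rr_series(arch, duration_s, seed)
    resp <- synthesize_resp(arch$resp_rate, 62.5, duration_s, seed = seed)
    ecg <- synthesize_ecg(rr, 250, seed = seed, snr_db = 25)
    ppg <- synthesize_ppg(rr, arch$ppg_morphology, 125, seed = seed,
                          ac_skew_target = arch$ppg_ac_skew_target)
    list(record = waveform_record(list(ecg = ecg, ppg = ppg, resp = resp)),
         rr = rr, arch = arch)
  })
}

# Four well-separated Gaussian blobs with the default mixture weights.
blob_data <- function(n = 400, sd = 0.7, seed = 5) {
  withr::with_seed(seed, {
    ctr <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), ncol = 2, byrow = TRUE)
    g <- sample(1:4, n, replace = TRUE, prob = c(0.267, 0.332, 0.276, 0.125))
    list(x = ctr[g, ] + matrix(rnorm(2 * n, 0, sd), ncol = 2), labels = g)
  })
}

# End-to-end pipeline runs on n=400 synthetic cohorts, shared between the
# K-selection and ARI acceptance tests.
e2e_runs <- function(seeds = 1:3, n = 400) {
  cached(paste0("e2e", paste(seeds, collapse = ""), "_", n), {
    lapply(seeds, function(s) {
      phenotype_cohort(cohort_config(n, seed = s), method = "ft_t", seed = s)
    })
  })
}
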