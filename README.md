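# physiophen

Waveform-based physiological phenotyping of critically ill sepsis patients.

Sepsis patients who satisfy the same clinical definition (suspected
infection plus an acute SOFA increase ≥ 2) can be in very different
autonomic and vascular states, and that heterogeneity is largely invisible
to intermittently charted vital signs. `physiophen` implements an
end-to-end pipeline that starts from short multichannel bedside waveform
segments — single-lead ECG, photoplethysmogram (PPG) and
respiratory-impedance (RESP), five minutes per patient — and:

1. extracts a **192-marker physiomarker panel**: heart-rate-variability
   indices (time-domain, Lomb–Scargle spectral, entropy / fractal /
   Poincaré / fragmentation), PPG pulse morphology and timing (amplitudes,
   normalized areas, widths at 25/50/75% of the pulse height, dicrotic
   notch measures, derivative-waveform features, pulse covariance
   spectrum), respiratory cycle dynamics, and ECG–PPG coupling
   (pulse-arrival time);
2. cleans the feature table (outlier masking at |z| > 6, > 15%-missingness
   filter, chained-equation imputation with predictive mean matching,
   near-constancy and |r| > 0.85 correlation filters, standardization);
3. learns a 32-dimensional representation with a **feature-tokenizer
   transformer autoencoder** (one token per scalar feature plus a CLS
   token; 3 blocks, 4 × 32-dimensional heads, MSE reconstruction;
   PCA / variational-autoencoder / identity baselines included);
4. projects to 2-D (UMAP, `n_neighbors = 30`, `min_dist = 0.1`) and runs
   **consensus clustering** (100 × 80% resampling, Ward linkage,
   K = 2–8), choosing the number of phenotypes from the consensus CDF
   (minimal proportion of ambiguous clustering) and assigning final labels
   from the consensus matrix itself with per-patient confidences;
5. distills the phenotypes into an XGBoost classifier with exact tree-SHAP
   explanations (top-20 discriminative markers per phenotype with effect
   directions);
6. stratifies outcomes: Kruskal–Wallis / chi-squared / summary-statistic
   one-way ANOVA group comparisons, Kaplan–Meier 28-day survival with
   log-rank tests, and day-2/7/28 prevalence tables for septic shock,
   vasopressor use and mechanical ventilation.

Because ICU waveform archives cannot be redistributed, the package ships a
**synthetic cohort generator** that plants four physiologic archetypes
(SP1–SP4: low-HRV/irregular, high-SDNN/low-complexity, high-SDNN/altered
pulse dynamics, high-pNN50/parasympathetic-dominant) with archetype-linked
covariates and outcomes, patient-level parameter heterogeneity, and full
ground truth — so the whole pipeline is testable end to end offline.

## A worked example

```r
library(physiophen)

# a 400-patient synthetic cohort, 5-minute ECG/PPG/RESP per patient;
# the full chain takes a few minutes on one CPU
cfg <- cohort_config(n_patients = 400, seed = 1)
res <- phenotype_cohort(cfg, method = "ft_t", seed = 1)

res$k_selected
#> [1] 4
round(res$ari, 2)        # agreement with the hidden archetype labels
#> [1] 0.98
table(archetype = res$metadata$archetype, phenotype = res$labels)
#>          phenotype
#> archetype   1   2   3   4
#>       SP1   0 100   0   0
#>       SP2 125   0   0   0
#>       SP3   2   0 125   0
#>       SP4   0   0   0  48
```

The consensus step selects four phenotypes and they coincide with the
planted archetypes up to two boundary patients (adjusted Rand index 0.98).
Outcome stratification runs off the same object:

```r
strat <- stratify_outcomes(res$metadata, res$labels)
round(subset(strat$prevalence, outcome == "ss" & day == 28)$rate, 2)
#> [1] 0.11 0.34 0.39 0.38
round(strat$logrank$p_value, 3)
#> [1] 0.685
```

The day-28 septic-shock gradient reproduces the planted risk ordering
(phenotype 1 = the low-risk SP2 archetype at 11%, phenotype 3 = SP3 at
39%). The 28-day log-rank test is not significant here: with 400 patients
and planted mortality rates between 19% and 29%, the survival contrast is
genuinely underpowered — a faithful reminder that the published survival
separation relies on a cohort five times larger.

Single markers use the same machinery; for example, an RR series from the
high-SDNN archetype recovers its planted magnitude:

```r
rr <- generate_rr_series(default_archetypes()$SP2, duration_s = 120, seed = 1)
round(unname(compute_hrv(rr)["SDNN"]), 1)   # archetype target: 184.6 ms
#> [1] 180.5
```

Statistics from published summary tables can be checked without raw data:

```r
anova_from_summary(ns = c(580, 721, 601, 272),
                   means = c(32.073, 30.316, 32.099, 37.125),
                   sds   = c(24.766, 22.137, 28.133, 24.756))$p_value
#> [1] 0.0021
```

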