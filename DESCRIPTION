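Package: physiophen
Title: Waveform-Based Physiological Phenotyping of Critically Ill Sepsis Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering physiological phenotypes of
    sepsis from short multimodal ICU waveform segments (single-lead ECG,
    photoplethysmogram, respiratory impedance). Provides a synthetic cohort
    generator with four planted autonomic/vascular archetypes; a multimodal
    waveform interpreter (quality control, denoising, signal derivation,
    fiducial delineation, and a 192-entry physiomarker catalog spanning heart
    rate variability, pulse morphology and timing, respiratory dynamics, and
    ECG-PPG coupling); a feature-cleaning pipeline (outlier rejection,
    missingness filtering, chained-equation imputation with predictive mean
    matching, variance and correlation filters, standardization); tabular
    representation learning (feature-tokenizer transformer autoencoder, deep
    variational autoencoder, PCA, identity baselines); resampled agglomerative
    consensus clustering with CDF-based selection of the cluster number;
    gradient-boosted phenotype classification with SHAP explanations; and
    outcome stratification (Kruskal-Wallis, chi-squared, summary-statistic
    ANOVA, Kaplan-Meier and log-rank analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    signal,
    survival,
    cluster,
    xgboost,
    jsonlite,
    pROC,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
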