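---
title: "Waveform-based physio-phenotyping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Waveform-based physio-phenotyping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sepsis is physiologically heterogeneous: patients arriving at the same
clinical definition (suspected infection plus an acute SOFA increase of at
least 2 points) can be in very different autonomic and vascular states.
Bedside monitors continuously record single-lead ECG, photoplethysmogram
(PPG) and respiratory-impedance (RESP) waveforms, but routine care reduces
them to a heart rate and a respiratory rate. `physiophen` implements an
end-to-end pipeline that turns a short (five-minute) multichannel waveform
segment per patient into a large panel of *physiomarkers* — quantitative
indices of heart-rate variability (HRV), pulse morphology and timing,
respiratory dynamics and ECG–PPG coupling — and then searches for stable
patient subgroups ("physio-phenotypes") in a learned low-dimensional
representation of those markers, finally relating the subgroups to
28-day outcomes.

Because bedside waveform archives cannot be redistributed, the package
ships a synthetic cohort generator with four planted archetypes, so that
every downstream stage is testable end to end without any data download.

## The synthetic cohort generator

Each archetype (SP1–SP4) is a parameter bundle: heart-rate level, HRV
magnitude targets (SDNN, RMSSD, pNN50, LF/HF ratio, RR skewness, an
irregularity level), PPG pulse morphology (systolic-rise fraction, dicrotic
notch prominence, pulse-arrival delay), respiratory rate, and
archetype-linked probabilities (28-day mortality; septic shock, vasopressor
and ventilation flags at days 2/7/28; qSOFA-style covariate prevalences).
The statistical targets are per-phenotype medians of a published sepsis
cohort characteristics table; quantities that table does not print were
fixed once at clinically plausible values consistent with its directional
statements (worst support burden in SP3, least in SP2, ventilation
second-highest in SP1) and are documented in
`inst/extdata/archetype_params.csv`.

RR intervals follow an additive model: a base period from the heart-rate
target, a low-frequency (LF) and a high-frequency (~0.25 Hz, respiratory)
sinusoidal modulation, stationary jitter whose autocorrelation encodes the
irregularity level, and a sparse positive "ectopic" jump process for
right-skewness. Amplitudes are calibrated analytically, in expectation:

* the white-jitter SD is chosen so that the fraction of successive
  differences above 50 ms matches the pNN50 target;
* the jump scale follows from the skewness target, capped at a quarter of
  the base period so jumped beats survive downstream artifact filtering;
* the remaining variance goes into the sinusoids at the LF/HF power ratio,
  with the HF amplitude capped by the pNN50 headroom.

One modelling consequence is worth stating plainly: interval SDs of
185–375 ms combined with single-digit pNN50 percentages (as the reference
table prints for some phenotypes) are only jointly realizable if the bulk
of the variance lives in *slow* modulation. The calibrator therefore lowers
the LF modulation frequency (still ≥ 0.01 Hz) until its beat-to-beat step
stays clear of the 50 ms pNN50 threshold. Only the smallest-SDNN archetype
(9.28 ms) is asserted quantitatively in tests (±25% on the extracted
median); for the others the cross-archetype orderings are asserted.

Every patient receives a *jittered* copy of its archetype (multiplicative
log-normal spread of 5–15% on rates and magnitudes, ±10 ms on the pulse
delay). Without this, all patients of an archetype would be statistical
replicas, and any discrete detail of the extraction chain (e.g. a bimodal
detector decision) would manufacture artificial, perfectly stable
sub-clusters. With it, within-phenotype physiology is a continuum around
the archetype signature, as in real cohorts.

ECG is synthesized as one Gaussian-sum PQRST complex per beat with
respiratory R-amplitude modulation (10% depth by default — the mechanism
ECG-derived respiration relies on), baseline wander below 0.3 Hz, and white
noise at a configurable SNR (20 dB default). PPG pulses have a half-cosine
upstroke, an exponential decay, and a Gaussian dicrotic bump whose
prominence is the archetype's notch parameter; per-beat AC amplitudes come
from a standardized-gamma family whose shape is solved from the skewness
target. RESP is a quasi-sinusoid with 5% period jitter. Outcome flags are
sampled as a first-activation day (day 2 implies days 7 and 28 — the
monotone-exposure reading), and death times are exponential with the rate
matched to the 28-day mortality, censored at day 28.

What the generator does *not* emulate: arrhythmia taxonomies, 12-lead
morphology, arterial-pressure waveforms, drifting signal quality,
treatment feedback on physiology, or covariate–waveform correlations
beyond the archetype level. Passing the recovery tests therefore shows the
pipeline can find the planted macro-structure under realistic noise — not
that it would find clinically true structure in real recordings.

## The waveform interpreter

Six stages, each a module function:

1. **Quality control** (`preprocess`): flatline detection (2 s rolling
   variance), rail-clipping runs ≥ 0.2 s, amplitude outliers |z| > 6
   (masked and interpolated), resampling to the configured uniform rates.
   A channel below 50% usable samples is flagged low-quality and its
   markers become missing values rather than errors.
2. **Denoising** (`denoise`): conservative despiking against a ~0.2 s
   running median (threshold 8 robust SDs, so QRS complexes survive), then
   a zero-phase Butterworth band-pass per channel (ECG 0.5–40 Hz, PPG
   0.5–8 Hz, RESP 0.1–0.5 Hz). The band-pass is a high-pass/low-pass
   cascade: the high-pass edge sits at a tiny normalized frequency where
   high filter orders are numerically fragile, so it gets order 2, while
   the low-pass keeps order 4; forward–backward filtering doubles both.
   The pre-filter DC level of each channel is retained as metadata so
   ratio markers (perfusion index) keep a physical denominator.
3. **Signal derivation** (`derive_signals`): ECG-derived respiration (cubic
   spline of per-beat R amplitudes on a 4 Hz grid), velocity and
   acceleration plethysmograms (Savitzky–Golay first/second derivatives).
4. **Delineation** (`delineate`): R peaks by derivative–square–integrate
   with an adaptive threshold and 200 ms refractory; PPG onsets at the
   minimum preceding each main VPG upstroke, systolic peaks, dicrotic
   notch as the first upward VPG zero crossing within 40–70% of the pulse
   (falling back to the slowest-decay inflection — the interior VPG
   maximum — which merges continuously with the vanishing notch as the
   diastolic wave weakens), diastolic wave, offsets; respiratory
   transitions as zero crossings of the mean-removed signal with per-cycle
   extrema.
5. **Marker extraction**: a 42-index interval-dynamics battery
   (time-domain, Lomb–Scargle spectral, entropy/fractal/Poincaré/
   fragmentation) applied to ECG NN intervals (HRV), PPG pulse intervals
   (pulse-rate variability) and — without the spectral block — breath
   periods; per-beat ECG wave series; per-pulse PPG/VPG/APG morphology and
   timing series; ECG–PPG coupling (pulse-arrival times); per-cycle
   respiratory series; and the eigenvalue spectrum of the covariance of
   pulses resampled to a common length. The default catalog totals exactly
   192 unique marker definitions.
6. **Summarization** (`summarize_series`): 16 statistics per time-varying
   marker, of which five are retained for analysis (mean, 25th/75th
   percentiles, skewness, histogram Shannon entropy with Freedman–Diaconis
   bins). Interval-battery indices are already aggregates and bypass this
   stage.

Numerical conventions that matter: NN filtering removes intervals outside
300–2000 ms and successive changes above 30% (a standard artifact rule the
source text does not specify); spectral powers are reported as normalized
fractions (LF and HF relative to the 0.003–0.40 Hz band, the total power
as the band's share of tachogram variance) because the reference table's
total-power scale (~0.086) is only representable as a dimensionless
fraction; entropies use m = 2, r = 0.2·SD (a five-minute window yields
only ~300–500 beats); sample entropy returns its conventional finite cap
−log(2/(N(N−1))) when no template matches; the Katz fractal dimension of a
constant series is defined as 1; the area normalization for pulse areas is
area/(duration × amplitude), the only reading under which the two
normalized sub-areas need not sum to 1, as the reference values require.

## Feature pipeline

Step order is fixed: outlier rejection (|z| > 6, strict), missingness
filtering (> 15%), chained-equation imputation with predictive mean
matching, near-constancy filtering, iterative correlation reduction
(|r| > 0.85), standardization. Choices worth recording:

* The imputer regresses each incomplete column on its ten most correlated
  predictors with a small ridge stabilizer — at p comparable to n a full
  regression is singular — and draws donors among the five closest
  observed predictions, so imputed values always lie in the observed
  support. A single completed dataset is returned (the downstream
  embedding consumes one matrix; no pooling).
* "Near-zero variance (SD < 0.01 after standardization)" is
  self-contradictory (post-standardization SDs are 1); it is read as
  raw-scale near-constancy: dominant-value share > 99% or raw SD < 1e−8.
* The published drop rule for correlated pairs ("retaining the feature
  with higher mean absolute correlation") inverts standard practice; the
  conventional direction is the default and a flag restores the quoted
  one.
* Covariate indicators (SBP ≤ 100, RR ≥ 22, GCS < 15, and their 0–3
  composite) are exempt from the variance and correlation filters by
  default, since the composite correlates with its parts by construction.

## Representation learning

The core learner is a feature-tokenizer transformer autoencoder: each
scalar feature is affinely mapped to a 128-dimensional token, a learnable
CLS token is prepended, learnable feature-identity embeddings are added,
and three post-norm encoder blocks (4 heads × 32 dimensions, 256-unit ReLU
feed-forward, dropout 0.1) process the sequence; the CLS output is
projected to a 32-dimensional latent vector from which a two-layer decoder
reconstructs all features. Training uses Adam (initial rate 0.002), halves
the rate after 6 stagnant validation epochs, and stops 20 stagnant epochs
after the best validation loss, restoring the best weights; the validation
split is a seeded 80/20 row split. Forward and backward passes are written
out explicitly in R and verified against central finite differences in the
test suite (the environment provides no tensor-autodiff library, and the
model itself is the package's core contribution, so owning the arithmetic
is deliberate).

Baselines: PCA (32 components), a Gaussian-latent variational autoencoder
(272→128→64→32 mirrored, KL weight 1 — the published architecture details
live in an unavailable supplement, so this stands as the package's
assumption, config-exposed), and the identity ("no transformation").

Cohort-scale runs train the transformer with a reduced budget
(`max_epochs = 20`, early stop 8, via `embed_features()`): the recovery
experiments need a representation that preserves the planted macro-
structure, which this model does within a few epochs, and the experiments
must fit a single-CPU session. The full early-stopping protocol with
`max_epochs = 200` remains the `encoder_config()` default.

## Projection and consensus phenotyping

Embeddings are projected to 2-D before clustering (clustering the raw
latent space directly was reported unstable in the source analysis, and we
follow that design). The primary backend is UMAP
(`n_neighbors = 30`, `min_dist = 0.1`, Euclidean), executed through the
python `umap-learn` implementation in a subprocess with a fixed
`random_state` and a single worker (no R-native UMAP implementation is
available to the package); `project_batch()` amortizes the interpreter
start-up across runs. A pure-R spectral fallback (Laplacian eigenmaps on a
Gaussian-weighted kNN graph with a weak global coupling term that keeps
the graph connected) is provided for dependency-free use.

Consensus clustering follows the resampling recipe: 100 iterations, each
drawing 80% of observations without replacement, Ward linkage, K = 2–8;
the consensus of a pair is the number of co-clusterings over the number of
co-samplings (pairs never co-sampled stay undefined and are excluded from
the CDF). The empirical CDF of the off-diagonal consensus values is
summarized two ways: its area (lower Riemann sum — the right-endpoint sum
degenerates to exactly 1 for any binary consensus) and the proportion of
ambiguous clustering, PAC = CDF(0.9) − CDF(0.1).

**Choosing K.** The relative CDF-area gain rule (largest K with
ΔAUC > 0.025) was implemented and then falsified on controlled data:
resampled Ward partitions of compact 2-D projections split even a
point-mass cluster *consistently*, so every additional K adds a few
percent of CDF area and the rule runs to the top of the K range for
cleanly separated four-cluster data. The PAC form of the same plateau idea
discriminates sharply — PAC is ~0 for every K up to the true number of
clusters and jumps when a genuine cluster must be split — so the default
rule is the canonical minimize-PAC criterion with two guards: ties within
0.01 of the minimum resolve to the largest near-minimal K (exact-zero
plateaus are common below the true K), and a minimum above 0.1 means no
unambiguous partition exists, in which case the smallest candidate K is
returned flagged unstable. The ΔAUC rule remains available
(`select_k(rule = "delta_auc")`).

Final labels do not come from a single clustering run: the consensus
matrix at K* is itself clustered (average linkage on 1 − consensus,
undefined entries imputed by column means), and each patient's confidence
is its mean consensus with its co-members.

One robustness rule sits above these stages in the cohort driver.
Occasionally the transformer lands in a poor optimum whose latent space
fuses two genuine clusters; validation reconstruction loss does not flag
these runs (a fused-cluster run and healthy restarts can sit at the same
validation MSE), but the consensus CDF does — no unambiguous plateau
exists beyond the smallest K. When the minimal PAC over K > k_min exceeds
0.05, the driver trains one restart from a derived initialization and
keeps the solution with the smaller residual ambiguity. This is the same
stability axis the representation comparison itself uses to rank methods,
applied as label-free model selection; it never sees the ground truth.

## Classifier distillation and explanation

An XGBoost multi-class model (softprob, library-default hyperparameters,
100 rounds, single thread) is trained on the cleaned, unstandardized
feature table against the consensus labels with a stratified seeded 80/20
split — stratification protects the ~12.5% smallest phenotype at moderate
cohort sizes. Explanations use the exact tree-path SHAP values the booster
itself computes (`predcontrib`), whose additivity (base value plus
attributions equals the class margin) is asserted in tests; per class the
top 20 features by mean |SHAP| are reported with a direction of effect
(sign of the correlation between feature value and attribution).
`export_interpretation_context()` emits the JSON context block a
downstream narrative-interpretation agent would consume; no language-model
call is made or implied.

## Outcome analysis

Kruskal–Wallis for continuous variables, chi-squared (no continuity
correction for k×2 tables; a flag enables Yates for 2×2) for categorical
ones, Kaplan–Meier with Greenwood plain-transform 95% intervals clipped to
[0, 1], the standard log-rank statistic, and day-2/7/28 prevalence tables
for the monotone support flags. `anova_from_summary()` reconstructs the
classic one-way F test from per-group sizes, means and SDs so that
published summary tables can be checked without raw data; it agrees with
`aov()` on simulated raw data to 1e−10, and the test suite verifies the
published mortality, age, platelet and blood-urea-nitrogen significance
levels from the printed summaries alone. Analyses treat one row as one
patient; the reference table mixes patient and encounter denominators in
its mortality row, a discrepancy we do not attempt to reproduce.

## Problem sizes used by the tests and the acceptance script

The recovery experiments run the complete chain — waveform synthesis,
extraction of all 192 markers, cleaning, transformer embedding, UMAP,
consensus — on n = 400 cohorts with the default mixture
(26.7/33.2/27.6/12.5%). The test suite runs three such end-to-end seeds and
requires a majority to select K = 4 and to recover the planted membership
at ARI ≥ 0.8; Monte-Carlo examples elsewhere use 3–10 seeds. Type-I-error
calibration uses 2,000 null replications per test. The acceptance script
performs one full end-to-end run at the given seed, distills the
classifier, stratifies outcomes, and recomputes the published-table
statistics; it writes all headline numbers as JSON.

## Known limitations

* The generator's archetypes are caricatures: they plant first-order
  statistical signatures, not mechanistic cardiovascular dynamics.
* Skewness targets for the large-SDNN archetypes are only partially
  reachable once jump sizes are capped for artifact-filter survival.
* The spectral-power normalization is one defensible reading of an
  ambiguous unit; absolute spectral powers are not comparable to
  ms²-scale HRV literature values.
* The transformer is CPU-bound R; it is adequate for cohorts of hundreds
  to a few thousand rows, not for large-scale training.
* UMAP determinism holds for a fixed seed and single-threaded execution;
  coordinates differ across `umap-learn` versions.
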