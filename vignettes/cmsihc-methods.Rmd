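---
title: "Methods: IHC-based CMS-resembling classification of colorectal tumors"
author: "cmsihc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IHC-based CMS-resembling classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

Transcriptome-based consensus molecular subtyping (CMS1 immune, CMS2
canonical, CMS3 metabolic, CMS4 mesenchymal) of colorectal cancer is too
costly for routine pathology. A practical surrogate assigns *CMS-resembling*
labels from immunohistochemistry on tissue-microarray (TMA) spots. `cmsihc`
implements that surrogate pipeline end to end:

1. **MMR gate.** Tumors with deficient mismatch repair (loss of any of
   MLH1/MSH2/PMS2/MSH6; consumed here as a boolean flag) are CMS1-like.
   The gate precedes everything else, so spot scores are ignored for dMMR
   tumors.
2. **Five-marker spot classifier.** Each of up to four 1-mm TMA spots is
   scored for CDX2, FRMD6, HTR2B, cytokeratin (KER) and ZEB1, and a
   logistic score converts the panel into a probability that the spot is
   epithelial-type. Majority vote across evaluable spots assigns
   CMS2/3-like (epithelial) or CMS4-like (mesenchymal); an exact tie is
   inconclusive and the tumor is excluded.
3. **β-catenin split.** CMS2/3-like tumors with a positive β-catenin
   nuclear consensus (score ≥ 2 in intensity *or* percentage category, per
   spot, majority across spots) are CMS2-like; negative ones CMS3-like;
   ties are excluded.

Around the classifier the package provides the scoring conventions
(intensity rounding, ZEB1 presence cut-off, compartment rules), the
model-versus-annotator validation metrics, Freeman–Halton exact association
tests, and survival machinery (Kaplan–Meier, log-rank, Cox with Efron ties,
Schoenfeld diagnostics) — all implemented in the package rather than
delegated, so every stage is testable against independent oracles.

## Scoring conventions

* **Rounding.** Continuous intensity on the 0–3 scale is rounded with
  half-up interval boundaries: 0–0.499 → 0, 0.5–1.499 → 1, 1.5–2.499 → 2,
  2.5–3 → 3 (`round_intensity()`).
* **ZEB1.** Entered as a presence indicator with a 2% cut-off; 2.0% counts
  as present (values below 2% are treated as staining noise).
* **Compartments.** CDX2/FRMD6 report intensity and percent in tumor
  epithelium; HTR2B intensity only; KER intensity and percent relative to
  the epithelium estimate; ZEB1 percent only; β-catenin nuclear intensity
  (0–3) and percent category (0–4: negative, 1–10%, 11–50%, 51–90%, ≥90%).
* **Tie-breaks.** A spot probability exactly at the threshold (default
  0.5) is called epithelial; the choice is deterministic and configurable.
  Patients with 1–3 evaluable spots are voted over the available spots —
  only ties and truly missing panels exclude a tumor.

## The spot model and its default coefficients

The published pipeline delegates the per-spot epithelial/mesenchymal call
to an external online calculator whose fitted coefficients are not public.
`classifier_model()` therefore exposes the same interface — a logistic
score over the eight panel features with ZEB1 as a presence indicator — as
a fully pluggable model. The default coefficients fix signs by marker
biology (CDX2, KER epithelial-positive; FRMD6, HTR2B, ZEB1
mesenchymal-positive), with magnitudes (±0.8 per intensity unit, ±0.02 per
percent point, −2 for ZEB1 presence, intercept 0) calibrated once against
the synthetic generator so that canonical epithelial and mesenchymal
panels fall beyond probability 0.9/0.1, and then frozen. They are a
working default, not a reconstruction of the original fit.

## Synthetic cohorts: the stated world

`generate_cohort()` draws a cohort whose defaults mirror the published
series: 538 patients, subtype prevalence (0.158, 0.349, 0.385, 0.108),
four 1-mm spots per tumor with 5% spot dropout, dMMR probability 0.95 in
CMS1-like and 0.02 elsewhere, and subtype-conditional clinicopathological
distributions taken from the published association table (so pM = 1 exactly
when stage IV). Marker intensities are drawn as truncated normals on the
*continuous* 0–3 scale and rounded downstream, mirroring the
regression-then-round flow and exercising the rounding rule; spots are
independent given the latent subtype — the simplest noise model that can
produce discordant spots and exercise majority voting and ties. β-catenin
intensity/percent categories are categorical draws per subtype with
per-spot positivity ≈0.98 for CMS2-like and ≈0.10 for CMS3-like.
Inter-spot marker spread (SD 0.35 intensity units, 8–10 percent points) is
a calibration choice: the source does not report the distribution of
discordant spots, so these defaults state a world in which discordance is
possible but majority votes are usually decisive.

Survival uses a Weibull (default exponential) proportional-hazards model:
baseline hazard 0.102/year (≈60% five-year survival in the CMS2-like
reference), subtype log hazard ratios (log 1.57, 0, log 1.45, log 1.45)
matching the published univariable effect sizes, independent exponential
censoring whose rate targets the requested censoring fraction in the
reference group (`censoring_rate = 1` censors everyone at time zero, 0
leaves only administrative censoring at the 15-year horizon), and
Bernoulli cause-of-death attribution (P(disease-specific | death) = 0.6),
making disease-specific events a subset of overall events by construction.
The attribution mechanism is a design choice; the source reports no
mechanism.

## Synthetic images and classical quantification

The CNN-based commercial scoring platform used by the source is
proprietary; the package replaces it with deterministic classical
operators that honor the same output contract. `generate_spot_image()`
renders a circular tissue disc (hematoxylin OD 0.35), epithelial blobs
(OD 0.9) and a DAB-positive fraction of epithelial pixels at OD =
level × 0.5 through a two-stain Beer–Lambert model with fixed unit stain
vectors, plus Gaussian 8-bit noise (default SD 2). Quantification inverts
exactly this model: least-squares stain separation, epithelium
segmentation by hematoxylin threshold (OD 0.6, between the stromal and
epithelial tones) with a 3×3 majority filter, mean DAB OD over positive
pixels (> 0.15 OD) mapped linearly back to 0–3, and percent positive as
the fraction of epithelial pixels above the positivity threshold.
Intensity is averaged over positive pixels only, keeping intensity and
percent independent. The 0–3 calibration (0.5 OD per unit) and the
positivity cut-off are package contract choices — the source does not
state how its continuous intensity is scaled before rounding.

The generator does **not** emulate nuclei-level texture, scanner
artifacts, stain variation across labs, or non-disc tissue geometry. A
green round-trip test therefore establishes that the quantification
operators invert the stated forward model at realistic noise — not that
they would score real slides like the original platform.

## Exact association testing

`fisher_exact_rxc()` implements the Freeman–Halton two-sided criterion:
the p-value is the total null (multivariate hypergeometric) probability of
all tables with the observed margins whose probability does not exceed the
observed table's, with a relative float-tie slack of 1e-7. Small tables
(≤ 1e8 candidate-table bound) are enumerated exactly with the last free
cell vectorised; larger tables use Monte-Carlo sampling of fixed-margin
tables (Patefield's algorithm via `stats::r2dtable`, which samples exactly
the null distribution) with the include-observed estimator
(hits + 1)/(reps + 1), default 10^6 replicates. On 2×2 tables the
criterion reduces to the classical two-sided Fisher test.

A transcription of the published covariate-by-subtype counts ships as
`table1_counts()`. Recomputing p-values from those counts reproduces the
printed values for age (0.027), sex (0.61), stage (0.47) and location
(<0.001). For pT, pN, pM, grade and histology the printed values are *not*
reproducible by any exact test: they agree to 3–4 significant figures with
Pearson chi-square p-values (0.249, 0.064, 0.50, 0.056, 0.001 vs exact
0.198, 0.101, 0.465, 0.063, 0.0004), indicating mixed transcription from
statistical software that prints both statistics. The package keeps the
faithful exact test; the corresponding acceptance assertions fail and are
documented rather than fudged.

## Survival machinery

All estimators are implemented in-package and validated against
independent oracles in the test suite (closed forms, brute-force grid
maximisation of the partial likelihood, a permutation oracle for the
log-rank test, and the `survival` package as a reference implementation):

* Kaplan–Meier with Greenwood variance and log-scale 95% intervals
  clipped to [0, 1].
* Log-rank across k groups via the observed-minus-expected statistic with
  hypergeometric variance (df = k − 1).
* Cox proportional hazards by Newton–Raphson with step-halving on the
  Efron-corrected partial likelihood. Efron (not Breslow) is the default
  because registry survival times in years are heavily tied and Efron is
  the accepted modern default; the source does not state its tie handling.
  Wald tests and intervals are reported (matching the HR (95% CI) + p
  presentation of clinical tables). Covariates are centred internally;
  non-convergence within 100 iterations flags the fit and suppresses
  hazard ratios; |β| > 15 triggers a separation warning.
* The enter-method pipeline enters *whole variables* whose univariable fit
  has any level with Wald p ≤ 0.05 jointly into the multivariable model —
  a categorical variable is selected if any of its levels is significant,
  matching how clinical tables enter whole factors. CMS2-like is the
  reference level for the subtype factor (`subtype_factor()`).
* Schoenfeld diagnostics: residuals at event times, scaled by m·V(β̂), and
  a Pearson correlation test against Kaplan–Meier-transformed time by
  default (raw time optionally); the source says only "across time", and
  the KM transform is the common robust default.

Published cohort-level hazard ratios and five-year survival percentages
are not reproduced: the underlying patient data are available only on
request from the original authors. The survival criteria are therefore
property-based — oracle agreement, parameter recovery at n = 2000
(log-HR 0.5 recovered within ±0.15 with ≥93% CI coverage), log-rank
type-I error within [0.03, 0.07], and Schoenfeld non-significance in ≥90%
of PH-true simulations.

## Numerical and design choices

* Exact-test tie slack 1e-7 (relative) avoids platform-dependent p-values
  at probability ties; the Monte-Carlo guard refuses `reps < 10^4`.
* The enumeration guard (≤ 1e8 candidate tables) keeps exact enumeration
  feasible for 2×c clinical tables while routing 3×4/4×4 tables with
  n ≈ 500 to Monte-Carlo.
* `perturb_annotation()` models annotator disagreement as a rigid shift
  drawn from a rounded normal (nonzero when jitter > 0). This is the
  simplest perturbation with strictly monotone expected F1 degradation;
  it does not model local boundary irregularity.
* Masks are logical matrices, origin top-left, row-major; exchanged as
  plain-text PGM (P2), images as plain-text PPM (P3), because no raster
  package is guaranteed in the deployment environment and netpbm text is
  lossless and diffable.
* Configuration and summaries use JSON; every pipeline run emits a
  manifest with the config snapshot, seed and output hashes, and re-runs
  with the same config are byte-identical on all tables.

## Known limitations

* The default spot model is a calibrated stand-in, not the original fitted
  classifier; absolute per-spot probabilities should not be compared to
  the online tool's output.
* Synthetic marker distributions are well separated; the ≥90% end-to-end
  recovery criterion certifies the pipeline's logic, not real-world
  classification accuracy.
* MMR status is consumed as a flag; interpretation of the four MMR protein
  stains is out of scope.
* Disease-specific attribution is an independent Bernoulli, so no
  competing-risks structure is modelled.
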