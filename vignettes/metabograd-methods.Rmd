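---
title: "Methods: differential abundance, surgical reversal and vascular gradients in plasma metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential abundance, surgical reversal and vascular gradients in plasma metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`metabograd` implements the statistical cascade of a plasma metabolomics
case-control study of chronic thromboembolic pulmonary hypertension
(CTEPH): semi-quantitative LC-MS intensities for a few hundred metabolites
across healthy controls (HC), disease controls (DC), chronic thromboembolic
disease without resting pulmonary hypertension (CTED),
idiopathic/heritable pulmonary arterial hypertension (IPAH/HPAH) and CTEPH
patients, with three auxiliary designs: a discovery/replication split of
the case-control contrast, paired and unpaired sampling around pulmonary
endarterectomy (PEA), and simultaneous sampling at three anatomical sites
(superior vena cava, pulmonary artery, radial artery).

The central container is the S4 class `MetabExperiment`, a
`SummarizedExperiment` with metabolites as rows and samples as columns.
Missing assay cells mean "below the limit of detection", not "not
measured": the missingness mechanism assumed throughout is left-censoring
at a per-metabolite detection limit, which is what justifies
minimum-detected imputation. A `scale_tag` records where the values stand
in the preprocessing chain (`raw`, `imputed`, `boxcox`, `zscore`,
`quantile_normalised`); operations validate their input scale and only
advance the tag forwards, so a matrix cannot silently be z-scored twice or
quantile-normalised before imputation.

# Preprocessing chain

The chain is `imputeMinDetected()` → `detectionFilter()` → `applyBoxCox()`
→ `zscoreToReference()` → `quantileNormalise()`, wrapped by
`preprocess()`.

**Imputation.** Each missing cell of metabolite *j* is set to the minimum
detected intensity of *j*. This is the canonical treatment under
left-censoring; it is biased upward for the censored truth but preserves
ranks, and every downstream test here is rank-based. Metabolites with no
detected value cannot be imputed and are dropped with a warning.

**Detection filter.** Only non-xenobiotic metabolites detected in at least
95% of samples (inclusive boundary: 19 of 20 samples qualifies) are kept.
The filter is judged on the *pre-imputation* mask, which
`imputeMinDetected()` stores as a second assay so the order
impute-then-filter still sees the original missingness. The threshold is a
tunable fraction in (0, 1].

**Box-Cox.** Per metabolite, `y = ((x + c)^λ − 1)/λ` (λ ≠ 0) or
`log(x + c)` (λ = 0), with λ maximising the profile log-likelihood
`−n/2·log(var(y)) + (λ−1)·Σ log(x + c)` over the grid −2 to 2 in steps of
0.1. The shift is `c = 0` unless non-positive values are present, then
`c = 10⁻⁶ + |min|`. The grid fit is deterministic and matches a reference
grid search (tested against `MASS::boxcox`). Ambiguity in whether
imputation precedes the transform is resolved as impute-first, so the
transform always sees a complete positive matrix. Because the transform is
strictly monotone per metabolite, all rank-based results (Mann-Whitney,
signed-rank, Spearman, AUC) are invariant to the fitted λ; the transform
matters only for the moment-based steps (z-scores, OLS adjustment, reported
means).

**Z-scoring to healthy controls.** Per metabolite,
`z = (y − mean_HC)/sd_HC`, so the HC subset has mean 0 and sd 1 exactly
(asserted at 10⁻¹² in the tests) and patient values read as sd-deviations
from health. Metabolites with zero reference sd are dropped with a warning.

**Quantile normalisation.** Every sample's values are replaced rank-wise by
the mean order statistics over all samples, removing between-batch
distributional shifts; afterwards all samples share one sorted value
vector, and the operation is idempotent. Ties within a sample receive the
mean of the reference values their ranks span, the convention that
preserves sample means (equal to `limma::normalizeQuantiles` on continuous
data, which the tests use as the reference implementation). Whether
z-scoring precedes or follows quantile normalisation is not dictated by the
design; the default here is quantile normalisation last, with
`qn_position = "before_zscore"` exposed because the alternative order is
equally defensible.

# Case-control cascade

**Mann-Whitney U.** `mannWhitney()` reports `U` (case-over-control pairs
plus half-ties), the probability-of-superiority `AUC = U/(n₁n₂)`, and a
two-sided p-value. For `n₁·n₂ ≤ 400` the p-value is exact: the null
distribution of the rank sum over all group relabellings is computed by
dynamic programming over doubled midranks (doubling keeps the grid integral
under ties), which reproduces full enumeration at polynomial cost and is
tested against `utils::combn` enumeration. Beyond that bound a
tie-corrected normal approximation without continuity correction is used;
the two branches agree to well under 0.01 at the boundary. When every
pooled value is tied the test is degenerate and returns p = 1, AUC = 0.5.

**Discovery/replication rule.** A metabolite passes only if its p-value
beats the Bonferroni bound α/m (α = 0.05 over the m retained metabolites;
m = 324 gives 1.54×10⁻⁴) in both cohorts *and* the effect direction (sign
of AUC − 0.5) agrees. Requiring two independent Bonferroni passes is
deliberately conservative; on global-null synthetic cohorts the family-wise
error of the rule is far below 0.05 (measured in the acceptance tests over
50 replicates).

**Confounder adjustment.** Screen survivors are refit by OLS:
`z ~ group + age + sex + ethnicity + BMI + preserved_renal +
preserved_liver + drug classes`, complete cases only, with metabolites
under 10 complete cases skipped. Creatinine and bilirubin enter as the
binary preserved-function indicators (< 75 µmol·L⁻¹ and < 21 µmol·L⁻¹
respectively) rather than as continuous covariates, because those cut-offs
are how the adjustment is defined clinically; healthy controls without
assay data are assumed preserved. Degenerate or collinear design columns
are dropped with a warning. The fit also reports
`|β_group|/|β_age|` and `|β_group|/|β_sex|`, the effect-ratio diagnostics
that contextualise how much larger the disease signal is than demographic
signals. One caveat surfaced by the synthetic studies: in a pure
case-vs-healthy contrast, drug-class indicators are near-proxies for case
status (patients medicated, controls not), which inflates the
group-coefficient standard error; this is a property of the design, not of
the implementation, and is why the adjusted criterion is nominal
(p < 0.05) rather than Bonferroni.

**Tiers.** `tierClassify()` assigns each metabolite the highest nested
specificity tier it fully meets: base (discovery + replication Bonferroni
vs HC, plus adjusted p < 0.05), then additionally adjusted p < 0.05 vs DC,
vs CTED, and vs IPAH/HPAH. Tier counts are monotone by construction and
the nesting is asserted in the tests.

# ROC evaluation

`rocCurve()` builds the empirical curve with one point per distinct
threshold (call = marker ≥ threshold), auto-negating the marker when the
raw AUC is below 0.5 and recording the flip. The trapezoidal area equals
`U/(n₁n₂)` to 10⁻¹². The "best" cut-off maximises Youden's
J = sensitivity + specificity − 1, with ties broken toward higher
sensitivity; Youden's J is a package decision, since no criterion is
dictated by the design. `aucInference()` gives the DeLong
placement-variance 95% CI (truncated to [0, 1]) — chosen over the
bootstrap for determinism — and a p-value against AUC = 0.5 taken from the
tie-corrected normal Mann-Whitney statistic, so the ROC and cohort modules
cannot disagree.

# Surgical reversal

`peaScreen()` is a two-stage cascade. Stage 1 contrasts independent
pre-surgery and post-surgery groups by unpaired Mann-Whitney under
Bonferroni control over the tested metabolites (mirroring the main cohort
analysis). Stage 2 validates stage-1 hits on subjects sampled at both
timepoints with `wilcoxonSignedRank()`: zero differences dropped (the
Wilcoxon convention, rather than Pratt's method), exact sign-flip
enumeration (again via dynamic programming over doubled midranks) up to 25
informative pairs, tie-corrected normal approximation beyond, with
`Var(W) = Σ rᵢ²/4`. Stage-2 significance is reported both nominally
(p < 0.05) and after Benjamini-Hochberg adjustment over the stage-1 hits at
FDR 0.05; neither correction is dictated by the design, so both are named,
configurable choices. Stage 2 is a subset of stage 1 by construction.

Reversal is summarised by `percentCorrection()`:
`100·(median(pre_z) − median(post_z))/median(pre_z)` on the HC-referenced
z scale, so 100 means full return to healthy-control level. Medians are
used rather than means for robustness to the skew that motivates the
rank tests; the statistic is undefined when the baseline perturbation is
negligible (|median(pre_z)| < 0.1) and is clamped to [−100, 200] for
reporting with the raw value retained. Hits whose unpaired and paired
directions of change disagree are flagged as probable screening false
positives — the situation the two-design comparison exists to catch.

# Gradients, enrichment, networks

`siteGradients()` tests downstream-minus-upstream differences following
flow (SVC→PA, PA→ART, and the systemic return ART→SVC) by paired
signed-rank over subjects with both sites sampled, reporting the median
paired difference in z-units. The sign convention is a documented flag;
all outputs name it. FDR is controlled by Benjamini-Hochberg within each
site pair across metabolites (three families, matching how per-gradient
FDR columns are reported); site pairs with fewer than 5 complete pairs are
skipped. On complete data the three mean differences close the cycle
exactly, which the tests assert.

`pathwayEnrichment()` runs a two-sided Fisher's exact test per pathway and
site pair — significant × in-pathway over all metabolites tested in that
pair — excluding pathways with fewer than 4 detected members. The p-values
are validated exhaustively against a hypergeometric-tail oracle.
`relevanceNetwork()` connects metabolites with Spearman ρ strictly above
0.9 (as printed; an absolute-value option exists) over the pooled
gradient-cohort samples — pooling all sites is a package decision, since
the sample set for the network is not dictated — and labels connected
components via `igraph`. `clinicalCorrelations()` rank-normalises each
clinical variable (normal scores) before computing Spearman ρ; the
correlation is invariant to that transform, so it only affects reporting
scales.

# Synthetic cohorts and the truth ledger

The generator exists to give every stage a ground truth. Its defaults are
the emulated study conditions: discovery 108 CTEPH vs 58 HC, replication
92 vs 63, DC 132, CTED 63, IPAH/HPAH 433; 64 pre- vs 82 post-surgery
unpaired plus 43 paired subjects; 68 + 18 subjects sampled at three sites.
Intensities are log-normal with per-metabolite log-sds drawn from 0.3–1
and within-subpathway correlation 0.3 via a shared latent factor (the
within-class correlation of real panels is not known from the design, so
the block strength is a free parameter). Effects are additive on the
natural-log scale — multiplicative on intensities, matching the
heavy-tailed positive nature of LC-MS data that motivates Box-Cox — and
expressed in sd units, so they read as z-scale shifts. Planted
case effects span the reported perturbation scale (decreases 0.33–1.53 sd,
increases 0.84–2 sd); age effects are 1/75 and sex effects 1/2.2 of the
group effect (the reported ~50–100× and 1.5–3.2× ratios); batch offsets are
N(0, 0.2) per metabolite per batch on the log scale. Missingness is
left-censoring at the per-metabolite 2% quantile, with a 5% subset of
metabolites given much higher detection limits (10–50%) so the detection
filter has real work; there is no missing-at-random contamination by
default. Specificity tiers are planted by letting comparator groups
"above" a metabolite's tier share the case effect, making the
case-vs-comparator contrast null. The surgery arm moves each responsive
metabolite's post values toward the HC mean by a planted fraction in
[0.15, 1], with within-subject noise of 0.4 sd, and can plant one
metabolite whose unpaired and paired shifts disagree. The tri-site arm
gives each subject a shared random effect (sd 1) with site offsets of
0.2–0.45 z-units accumulating along the flow direction and a between-site
residual of 0.15 sd — a value back-calculated from the magnitude of
gradients detectable at ~86 subjects in studies of this design — plus a
latent severity score that drives both the clinical variables and a subset
of metabolites.

Everything planted is recorded in a `TruthLedger` (validated: correction
fractions in [0, 1], finite effects), and all three generators are
deterministic under a seed.

What the generator does *not* emulate: chromatographic drift, adducts and
isotopes, missing-at-random dropout, non-log-normal intensity families,
correlated covariates (age×BMI), or informative missingness in the
clinical variables. Passing recovery tests therefore demonstrates that the
inference machinery is correct and calibrated under the stated assumptions,
not that those assumptions hold in any particular real dataset.

# Numerical choices and degenerate inputs

* Exact rank-test distributions use dynamic programming over doubled
  midranks; doubling keeps sums integral under midrank ties. Two-sided
  exact p-values are tail probabilities of |statistic − mean| with a 10⁻⁹
  slack against floating-point ties.
* All-tied group comparisons return p = 1, AUC = 0.5; all-zero paired
  differences return p = 1 with zero informative pairs.
* Quantile normalisation requires a complete matrix and refuses `NA`s.
* OLS adjustment drops constant and collinear design columns (QR rank
  check) with a warning rather than failing.
* `sample_id`/`metabolite_id` uniqueness, non-negative raw intensities and
  controlled vocabularies (group, cohort, timepoint, site) are enforced at
  container construction and file read, with errors naming the offending
  id or listing the allowed values.

# Problem sizes used by the test and acceptance suites

Unit tests run on 60-metabolite cohorts with group sizes of 20–90. The
calibration and recovery studies use 50 replicates at m = 300 with the
discovery/replication sizes above for the null cascade; 50 replicates at
m = 300, 100 cases vs 60 controls per cohort with 1.5 sd effects for
recovery; 50 replicates of the 43-pair surgery arm at m = 120 with 2 sd
perturbations for percent-correction recovery; and 50 replicates of the
86-subject tri-site arm at m = 150 for gradient sensitivity. The
acceptance script reports the same quantities from 10–20 fresh replicates
per arm. These sizes were chosen to estimate rates with adequate
Monte-Carlo precision while keeping a full run in the minutes range.

# Known limitations

* Percent correction is a ratio of medians; when the baseline perturbation
  is small the estimate is unstable, which is why it is flagged undefined
  below 0.1 z-units rather than reported.
* The discovery/replication rule is conservative by design; its power
  against effects well under 1 sd at these cohort sizes is limited, and
  the default effect distribution deliberately includes such effects.
* Quantile normalisation assumes samples share a common distribution up to
  batch shifts; strong true global shifts (e.g. a treatment moving many
  metabolites one way) would be partially absorbed.
* The OLS adjustment assumes linear covariate effects on the transformed
  scale and cannot separate group from a covariate that is (nearly)
  constant within groups, as the drug-class caveat above illustrates.
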