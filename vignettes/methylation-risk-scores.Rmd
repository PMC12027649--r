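---
title: "Methylation risk scores from mixed-model association: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation risk scores from mixed-model association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Endometrial methylation case–control studies sit in an awkward power
regime: case–control beta differences at individual CpG probes are small
(0.03–0.08 on the beta scale), so with cohorts of a few hundred samples
per site almost no single probe reaches epigenome-wide significance, yet
in aggregate the methylome carries a substantial fraction of the
case–control variance. A methylation risk score (MRS) — a weighted sum of
an individual's probe beta values with weights learned on training
samples — pools those sub-threshold signals into a single predictor that
can be evaluated on held-out cohorts, and compared or combined with a
polygenic risk score (PRS) to ask whether methylation carries information
beyond common genetic variants.

`methrisk` implements that full analysis: variance partitioning across
methylation and genotype relationship matrices, mixed-model per-probe
scans, BLUP weights, score construction, logistic evaluation with DeLong
intervals, and leave-one-institution-out (LOIO) cross-validation,
together with a synthetic cohort generator that emulates the multi-site
study structure and records its ground truth.

# Models

## Variance partitioning (OREML/GREML)

With `y` the 0/1 status vector, `X` fixed covariates and `A_k` a set of
sample × sample relationship matrices,

$$y \sim N\!\big(X\beta,\ \textstyle\sum_k \sigma^2_k A_k + \sigma^2_e I\big).$$

Each `A = ZZ'/m` is built from the samples × features matrix `Z` of
probe betas (ORM) or variant dosages (GRM) standardized to mean 0 and
*population* variance 1 (divide-by-n), so `mean(diag(A)) = 1` and
`trace(A) = n` exactly. One standardization scheme is used everywhere;
every downstream quantity is invariant to a global rescaling of `A`
combined with re-estimated variances, so nothing is lost by fixing the
convention.

`fit_variance_components()` maximizes the *restricted* likelihood.
Binary status is analysed on the observed 0/1 scale — phenotypic
variance estimates of about `p(1-p)` (≈ 0.2275 at a case fraction of
0.65) are expected — and no liability-scale transformation is applied.
The five-model ladder used in variance-partition reports (ORM alone; GRM
alone; ORM + GRM; SV-adjusted ORM + GRM; plus age/institution/cycle
covariates) is a set of argument combinations of this one function;
`variance_ladder()` wraps it. SV adjustment enters by residualizing the
beta matrix on surrogate variables *before* ORM construction, not as
fixed effects. `write_variance_report()` emits, per model, both each
component's own share and the plain sum of non-residual shares (the
"combined" convention), labelled separately.

## Per-probe scans

`moa_scan()` fits, for each standardized probe $w_i$,

$$y = w_i b_i + C\beta + Wu + e,$$

with the genome-wide random term `Wu` represented through the ORM. The
null-model variance components (no target fixed effect) are estimated
once and reused for every probe — the P3D ("population parameters
previously determined") approximation standard in mixed-model scans.
Each probe is then tested by GLS; the reported p-value is the two-sided
normal tail of `b/SE` for every scan method (the Wald contract). The
target probe remains inside the random term in MOA, costing a small
uniform shrinkage; `moment_scan()` removes it (and its neighbourhood):
probes are split by an initial OLS scan into a strong-effect group
(initial `p < group1_threshold`) and a background group, fitted as two
random components, and for each target all probes within 50 kb on the
same chromosome — a fully closed window, target included — are removed
from the random terms via a low-rank covariance downdate. A stepwise
reduction demotes the weakest strong-group probes (largest initial p, in
batches of 10% of the group) while the strong component's variance share
exceeds `share_cap` or its REML fails. If no probe passes the initial
cut, the grouping is empty and the model *is* the single-component MOA;
the implementation returns exactly the MOA result in that case.

`ols_scan()` is the fixed-effects baseline. Its Wald SE uses the
covariate-only residual variance shared across probes, which is the
exact `σ²_u → 0` limit of the mixed scan — so forcing the methylome
variance to zero reproduces OLS to machine precision, a useful identity
for testing. Coefficients are identical to per-probe least squares
either way.

## Weights and scores

Two weight routes feed the MRS:

* **Threshold selection** (`select_probes_by_threshold()`): scan probes
  with `p < τ` (strict inequality; a probe at exactly τ is excluded)
  contribute their per-SD effect as weight. The default grid is
  `{1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.5}`, configurable.
* **BLUP** (`blup_probe_effects()`): the individual-level joint probe
  effect `u` from `predict_individual_effects()` is back-solved to
  per-probe weights `b = Z'A⁺u/m` (pseudo-inverse tolerance `1e-10` of
  the largest eigenvalue). This equals ridge regression of the adjusted
  phenotype on `Z` with `λ = m σ̂²_e/σ̂²_u`, and every probe receives a
  weight — no thresholding.

`compute_mrs()` evaluates `MRS_i = Σ_k w_k m_ik` on **raw beta values**
of the test samples, over the intersection of weight and test probes
(absences counted, empty intersection fatal). Because scan weights are
per standardized probe, raw-beta scoring rescales each term by that
probe's training SD; for probes of comparable variance this changes
scale, not ranking. A `standardize = TRUE` switch scores on
train-standardized betas instead. `compute_prs()` orients each dosage to
the weight's effect allele (alt: `d`; ref: `2 − d`; neither: skipped and
counted) and returns the plain weighted sum — AUC is invariant to the
mean-score rescaling some tools apply. Strand-ambiguous (A/T, C/G)
variants are not reconciled; synthetic weights avoid such pairs by
construction and real data must be pre-harmonized.

## Evaluation

Per test set and weight specification, three logistic models are fitted:
MRS alone, MRS + PRS, PRS alone. AUCs come from the rank form of the
Mann–Whitney statistic (ties counted half); 95% intervals from the
DeLong structural-components variance, reported untruncated; p-values
are Wald (including `p_PRS` in combined models — a likelihood-ratio
variant would be a reasonable alternative, Wald is what is labelled).
Perfect separation (deviance < 1e-6 with diverging coefficients) is
flagged; the AUC of the raw score remains valid. Best-model selection
follows three ordered rules: models at thresholds 1e-4 and 1e-5 are
excluded (too few probes, unstable scores); among remaining models with
a significant MRS term (`p_MRS < 0.05` in the MRS-only fit) the highest
AUC wins; with no significant model, the highest AUC overall wins. Ties
break deterministically by fewer probes, then method name.

# Preprocessing conventions

* **m-values**: `m = log2(β/(1−β))` with β clipped to
  `[1e-6, 1−1e-6]` (warning). Linear modelling of methylation happens on
  this variance-stabilized scale; scores use raw betas.
* **PCA** (`pca_scores()`): projections onto the top right singular
  directions of the column-centered matrix; the sign of each component
  is fixed by making its first nonzero loading positive, so output is
  deterministic. Genetic PCs are this PCA applied to standardized
  dosages; 11 are retained by default and computed once on the full
  analysed cohort, not per split — a deliberate, documented leakage
  caveat that mirrors how population-structure PCs are computed once per
  study.
* **Covariate screening** (`covariate_screen()`): continuous covariates
  vs status by two-sided Welch t-test (the robust default when only
  "t-test" is specified); categorical by chi-squared without continuity
  correction, switching to Fisher's exact test when any expected cell is
  below 5; methylation PCs (top 15) vs covariates by one-way ANOVA or a
  simple-regression F-test.
* **Surrogate variables** (`estimate_svs()`): each probe's m-values are
  residualized on intercept + status; the number of SVs `q` is the count
  of leading singular values exceeding the 95th percentile of 20
  column-permutation nulls (each permuted matrix re-residualized, its
  top singular value found by power iteration); the top-q left singular
  vectors are refined by one reweighting pass that emphasizes probes
  whose residual variance the SVs explain, then re-orthonormalized.
  Columns are zero-mean (they live in the residual space of the
  intercept), unit-norm and orthogonal. The permutation-based dimension
  estimate is self-contained and testable; it is this package's own
  choice where the literature offers several estimators. SVs are
  estimated separately within training and test sets in the pipeline;
  by default training SVs enter the scans as fixed covariates
  (`sv_in_covariates`), with pre-residualization of the beta matrix as
  a config alternative (`sv_preresidualize`), and the MRS itself is
  computed on raw betas.

# Numerical choices

REML is maximized in the **error-contrast space**: with `K` an
orthonormal basis of the orthogonal complement of `col(X)`, the REML
projection satisfies `P = K (K'VK)^{-1} K'`, so the likelihood, scores
and average-information matrix are computed from `K'y` and `K'A K`.
This matters because centred features make every relationship matrix
exactly singular along the all-ones vector; the textbook
`log|V| + log|X'V^{-1}X|` evaluation suffers catastrophic cancellation
near the residual-variance boundary, while the contrast form stays
well-conditioned. The reported log-likelihood is shifted by
`−log|X'X|/2` to the classical convention so it is directly comparable
with dense-formula implementations. Updates are average-information
steps with step-halving, an EM first step, and EM fallback whenever an
AI step fails to increase the likelihood; variances are floored at
`1e-8 × var(y)` (non-negativity); convergence is a restricted
log-likelihood change below 1e-8, with a 100-iteration cap flagged on
the result. SEs come from the inverse AI matrix; proportion SEs by a
first-order delta method and are approximate. An AI condition number
above 1e8 flags non-identifiability (e.g. an identity "relationship"
matrix, where only σ²_u + σ²_e is determined). The same contrast
representation drives the MOA and MOMENT GLS tests, which also makes
the per-target 50 kb downdate a pure Woodbury update of `K'VK`.

Degenerate inputs are handled explicitly: zero-variance probes are
dropped (all-zero is fatal), empty weight sets warn and are rejected by
the scoring step, a single analysed institution is fatal for LOIO,
splits missing a class are skipped with a warning, and institutions
with fewer than 10 samples produce warned-but-usable splits. Scores,
scans and the pipeline are deterministic given the config seed; the
only internal randomness (the SV permutation null) is seeded from it.

# The synthetic cohort generator

`simulate_cohort()` emulates the study structure the pipeline assumes:

* **Design**: 908 samples by default across four institutions with
  sampling proportions 9/33/17/41%, case fraction 0.65 via a
  liability-threshold model (the analysis itself is observed-scale;
  the generator needs a causal scale, so recovery targets are computed
  from realized observed-scale quantities, and
  `simulate_orm_phenotype()` provides a direct observed-scale fixture
  for REML recovery tests).
* **Genotypes**: dosages `Binomial(2, MAF)` with MAF uniform on
  [0.05, 0.5]; all variants carry liability effects scaled so the
  variant share equals `h2_snp_liability` (default 0.25). Ref/alt pairs
  avoid strand-ambiguous combinations.
* **Methylation**: probe baselines uniform on [0.1, 0.9] with i.i.d.
  Gaussian noise (`probe_noise_sd`, default 0.08); `n_differential_probes`
  (default 50) receive a case–control mean shift drawn from
  [0.03, 0.08] through a non-genetic disease factor; `n_mqtl_probes`
  receive dosage-proportional shifts (sd 0.02 per dosage unit);
  institution offsets (sd 0.01) and clipping to [0.001, 0.999] (keeps
  m-values finite) apply to all probes. Differential-probe baselines
  are drawn mid-range ([0.15, 0.70]) so clipping cannot attenuate the
  planted shift. `var_meth_nongenetic` sets how much of the disease
  factor's variance is status (default 0.8; the remainder is
  individual-level jitter) — the case-minus-control mean shift equals
  the recorded truth either way.
* **Covariates**: cases average 2.8 years younger (34.2 vs 37.0);
  cycle-phase and ancestry labels follow study-like marginal
  proportions, drawn independently of status. Institution assignment is
  also independent of status — the real design's institution–status
  association is not emulated, only the marginal proportions.

The default `probe_noise_sd = 0.08` places per-probe effects in the
low-power regime the analysis is designed for: a 0.05 shift against an
0.08-sd probe gives modest single-probe test statistics at n ≈ 900,
while the 50-probe aggregate carries a large but non-degenerate share
of status variance. Much smaller noise makes the planted panel
near-deterministic for status — a regime in which the training REML
legitimately runs to its boundary and which no real endometrial cohort
resembles.

What the generator does **not** emulate: array chemistry and probe
cross-hybridization, cell-type composition, correlated probe
neighbourhoods (probes are independent apart from the planted shared
factors; the 50 kb exclusion is therefore exercised structurally, not
against real local correlation), imputation uncertainty, and
institution–status confounding. Passing recovery tests on these cohorts
therefore demonstrates correctness of the estimators under the stated
model, not robustness to everything real data can do.

# Problem sizes used by the test suite

The suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical contracts are comfortably
testable: REML recovery uses 20 cohorts of n = 500, m = 2000 (planted
share 0.5); scan calibration uses 10,000 null probes at n = 500 and a
polygenic cohort (n = 500, m = 2000, share 0.8) in which OLS inflates
(median-based λ ≈ 1.2–1.3) while the mixed scan stays within
[0.9, 1.1]; cross-method coherence uses n = 400, m = 800; the
end-to-end LOIO runs use n = 900, 1000 probes, 300 variants, four
institutions, with 50 planted probes at shift 0.05 (signal) and none
(null). Oracle equivalences run on 15–30-sample fixtures against dense
implementations.

# Known limitations

* Proportion SEs are first-order delta approximations; near the
  boundary (shares close to 0 or 1) they understate uncertainty.
* P3D is an approximation: per-probe variance re-estimation is not the
  default (and not implemented as a fast path); for strong single-probe
  effects the reported SEs are slightly conservative.
* The MOMENT stepwise parameters (`group1_threshold`, `share_cap`,
  batch size) are explicit stand-ins for a procedure whose reference
  implementation does not document its rule; they are config keys, and
  conclusions should not hinge on their exact values.
* Observed-scale variance shares are not converted to the liability
  scale.
* `compute_prs()` assumes pre-harmonized strands and one weight row per
  variant; no clumping or correlation-aware reweighting of probes is
  attempted.
* With very small test institutions (tens of samples) DeLong intervals
  are wide and the best-model selection is noisy across the grid; the
  LOIO design reports them per split rather than pooling.
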