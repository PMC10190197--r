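---
title: "Methods: stratified analysis of UDCA treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified analysis of UDCA treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(udcaresponse)
```

## The scientific problem

Primary biliary cholangitis (PBC) is treated first-line with ursodeoxycholic
acid (UDCA), but a large minority of patients do not respond. Dynamic
response is judged from alkaline phosphatase (ALP): under the Barcelona
criterion a patient responds if ALP falls by more than 40% of the
pre-treatment value or normalises (drops to or below the hospital's upper
limit of normal, ULN) after at least a year of treatment. A further
prognostic threshold — post-treatment ALP above 1.67 x ULN (the
Toronto/POISE bad-prognosis cut-off) — identifies a small paradoxical
subgroup of dynamic responders with persistently elevated ALP. This package
calls the three groups `NR`, `R` and `R_BP`:

* `R`   — (1 - ALP_post / ALP_pre) > 0.40 **or** ALP_post <= ULN;
* `R_BP` — `R` and ALP_post > 1.67 x ULN;
* `NR`  — everyone else.

Both comparisons are strict inequalities; `classify_response()` applies them
per patient, and the ULN is hospital-specific because ALP assay kits differ
between recruiting centres. The same subgroup can be seen non-parametrically:
with a uniform ULN, the `R`-group ALP values above the upper Tukey fence
(Q3 + 1.5 IQR, `tukey_outlier_fence()`, type-7 quantiles by default since no
convention is canonical — the convention is configurable) coincide with the
1.67 x ULN exceedances.

Around this classification the package implements the full downstream
analysis battery used in cohort studies of UDCA response: the
cohort-characteristics table with its mixed test family, LC-MS bile-acid
preprocessing, NMR normalisation, compositional 16S statistics, marginal
PERMANOVA variance partitioning, per-feature mixed-model association
testing, confounder matching for the small `R_BP` group, and a
taxon-metabolite correlation screen — plus a synthetic-cohort generator
that makes every stage testable end to end with known ground truth.

## The cohort table battery

`build_table_one()` summarises a classified cohort per group and attaches,
per variable, the test a clinician-statistician would use: the exact r x c
Fisher test for categorical rows, one-way ANOVA for approximately normal
continuous rows (ALP, bilirubin, ALT and platelet count on the log10
scale), and Kruskal-Wallis for treatment years.

`fisher_exact_rxc()` is authored here rather than delegated because the
printed reference tables are 2 x 3 and 3 x 3 with n = 419, and the exactness
of the reproduction is the point. The two-sided p-value is the sum of
probabilities, under the hypergeometric product model with fixed margins, of
all tables no more probable than the observed one (relative tie tolerance
1e-7, since float ties between table probabilities are ubiquitous). Only
the (r-1)(c-1) free cells are enumerated; rows and columns are sorted by
increasing margin so the small margins bound the outer loops, infeasible
ranges are pruned, and the innermost cell is evaluated as a vector. The
3 x 3 smoking table (n = 419) enumerates ~8 x 10^5 tables in well under a
second. An enumeration budget (`max_tables`, default 1e8) turns pathological
inputs into an explicit error recommending Monte-Carlo approximation.

`oneway_anova()` accepts either raw groups or summary triples (n, mean, sd)
and computes both through the same decomposition, so published tables — which
print only means and SDs — can be re-tested. Means rounded to 2 decimals
move the resulting p-values by a few thousandths; this is the tolerance used
when comparing to printed values. `two_sample_t()` defaults to Welch because
published "t-test" labels rarely state the variance assumption and Welch is
safer under unequal variances; the Student variant is one argument away.

Missing clinical covariates are imputed as in the source procedure
(`impute_clinical()`): modal category for categorical gaps; missing BMI
regressed on weight and sex when weight is available (the two are nearly
collinear); sex-specific median BMI otherwise. The imputed row indices are
recorded so that matching can refuse imputed BMI values.

## LC-MS preprocessing

`preprocess_ms()` enforces a fixed stage order: drift correction ->
two-stage QC filtering -> fecal-mass normalisation -> bile-acid family
sums -> log transform with left-censored imputation and mean-centring.

**Drift correction** (`drift_correct_loess()`). Electrospray signal decays
along an acquisition run. Pooled QC aliquots injected at the start, end and
evenly through the run all share one true profile, so their total ion
intensity traces the drift. A loess smooth (span 0.75, degree 2 — the
smoother is named in the field's protocols but its parameters are not, so
these common defaults are exposed as arguments) of QC TIC against run order
is evaluated at every injection, normalised to mean one, and divided out.
Beyond the QC range the smooth is extended linearly from the boundary slope.
Normalising to mean one makes the correction scale-equivariant; with too few
QCs for the span the fit falls back to a global polynomial.

**Filtering** (`apply_feature_filters()`). Stage 1 removes features below
the limit of detection in more than 90% of QC samples; stage 2 removes
survivors with QC coefficient of variation above 30% or below LOD in more
than 20% of study samples. Censored (`NA`) entries count as below LOD. When
no instrument LOD is supplied, the per-feature default is half the minimum
positive QC intensity — an operational stand-in, since protocols rarely
define LOD numerically. QC CV is computed on drift-corrected intensities
(the stage order implies it; computing it pre-correction would conflate
drift with analytic noise).

**Left-censored imputation** (`log_impute_center()`). Below-LOD values are
missing-not-at-random from the lower tail. Per feature, a normal
distribution is fitted to the observed log intensities by regressing their
order statistics on the normal quantiles of the upper (1 - censored
fraction) of the distribution — a quantile-based fit that is unbiased under
left censoring, in the spirit of quantile-regression imputation of
left-censored data — and imputed values are drawn from the fitted lower
tail truncated strictly below the feature's observed minimum. Draws are
seeded; the imputed mask is returned. Features with fewer than three
observed values are an error rather than a silent guess.

**Family sums** (`compute_ba_families()`). Glycine- and taurine-conjugated
totals, per-compound conjugated + unconjugated totals and the total
bile-acid sum are computed on the pre-log intensity scale ("summed
intensities" implies the intensity scale) and appended before the log
transform, so families flow through imputation and centring like any other
feature. A censored member contributes nothing to a family sum; a family
with every member censored stays censored and is imputed downstream.

**NMR side.** `pqn_normalize()` implements probabilistic quotient
normalisation: each spectrum is divided by the median, over features, of
its quotients against the median reference spectrum. `peak_auc()` computes
the trapezoidal area of a representative peak over a ppm window with linear
interpolation at the window edges.

## Compositional 16S statistics

Counts are compositions: only ratios carry information. The processing
chain is `prevalence_filter()` (keep taxa present in >= 10% of samples) ->
`gbm_zero_replace()` -> `clr_transform()`.

Zero replacement follows the Bayesian-multiplicative scheme: a zero cell of
part j in a sample with total n receives the prior-based pseudo-proportion
t_j * s / (n + s), and the observed parts are multiplied by one minus the
total replaced mass, which preserves their ratios exactly — the defining
property of the multiplicative variant, and the reason clr coordinates of
observed parts are undisturbed. The default prior proportions t are the
renormalised geometric means of each part's positive proportions across
samples (the "geometric" in geometric Bayesian-multiplicative), and the
default strength is s = sqrt(n), the square-root convention that keeps the
replaced mass a vanishing fraction of realistic library sizes. Both are
arguments: published defaults for this method's hyperparameters are not
stated, so the choices are explicit and overridable rather than buried.

Alpha diversity (`alpha_diversity()`) is computed on raw, unfiltered
counts: richness, Shannon entropy (nats), Simpson concentration D = sum
p^2, Pielou evenness H / log(S), and Simpson evenness (1/D)/S. Both the raw
Simpson form and its evenness are reported because group comparisons in the
literature use either; which one drives a downstream test is the caller's
choice. Faith's phylogenetic diversity (`faith_pd()`) sums branch lengths
over the minimal subtree spanning the observed taxa and the root,
implemented with a sparse edge-by-tip incidence matrix so that hundreds of
samples against a ~10^4-tip tree stay inexpensive; a positive root edge, if
the tree carries one, is included for non-empty samples. Beta-diversity is
viewed through PCA of the clr matrix (`pca_scores()`, SVD on
column-centred data), the standard Euclidean/Aitchison view.

## Variance partitioning

`permanova_single_factor()` implements marginal PERMANOVA: the factor is
the *only* predictor, so R^2 is the total variance attributable to that
factor alone, deliberately not a sequential or conditional decomposition.
The squared Euclidean distance matrix is Gower-centred to G; SS_total =
tr(G); SS_factor = tr(HGH) for the factor's hat matrix (computed through
the block identity for categorical factors and the centred single-column
projection for continuous ones — continuous covariates like age and BMI
enter as one regression column); pseudo-F = (SS_f/df1)/(SS_res/df2). The
p-value permutes sample labels: p = (1 + #{F_perm >= F_obs}) / (1 + n_perm),
seeded, with the permutation floor 1/(1 + n_perm) respected. With n! <=
10,080 all relabelings are enumerated and p is exact. The default n_perm =
999 follows the convention of the standard distance-based tools.
`variance_table()` runs one marginal model per factor and applies
Benjamini-Hochberg across the factor family of each omics matrix
(significance flagged at adjusted p < 0.1), matching the per-matrix
presentation of such analyses.

## Per-feature association testing

`fit_feature_lmm()` fits `feature ~ response + covariates + (1 | hospital)`
by maximum likelihood via `lme4::lmer` — the same engine the field uses —
with continuous covariates mean-centred and unit-scaled. REML is off
throughout because likelihood-ratio tests on fixed effects are invalid
under REML. Boundary (singular, tau^2 = 0) fits are legitimate ML solutions
and are *not* flagged as failures; only genuine optimizer non-convergence
is, and such features are reported with `NA` p-values and excluded from the
multiplicity family so they cannot bias the FDR. `lrt_response()` forms
Lambda = 2(l_full - l_null), clipped at zero, against chi-square with df =
number of response dummy columns (2 for three groups). `test_features_lmm()`
drives the per-feature loop and applies BH at 10% FDR.

For the matched subset, `da_clr_lm()` is a deliberately transparent
stand-in for bias-corrected compositional differential-abundance tools: clr
abundances regressed on response + age + BMI (only those two covariates,
because the matched subset is small), omnibus F test, Holm adjustment at
0.1. It inherits clr's invariance to per-sample count rescaling but applies
no sampling-fraction bias correction; the output carries a metadata label
saying exactly that.

`structural_zero_fpr()` quantifies why structural-zero detection is
disabled for small groups: with per-sample presence Bernoulli(pi), the
probability that some group is all-zero by chance while the taxon is
genuinely present everywhere decays geometrically in the per-group n (for
two groups it is 2q(1-q) with q = (1-pi)^n, the closed form the simulation
is tested against). At pi = 0.1 the rate falls from ~0.69 at n = 10 to
~0.014 at n = 50 — the basis for requiring on the order of 50 samples per
group; the function exposes the whole curve and leaves the acceptability
threshold to the user.

`correlation_screen()` computes all pairwise Pearson correlations between
taxa and metabolite features, BH-adjusts across all pairs, and reports a
pair only when adjusted p < 0.1 *and* |r| >= 0.2 — the magnitude filter is
applied on top of, not instead of, significance.

## Confounder matching

`encode_scale_covariates()` converts the matching covariates (sex, age,
BMI, sequestrants, smoking, PPI, antibiotics, hospital) to integers —
documented orders: smoking never < former < current, alcohol abstinent <
moderate < excess, sex female < male, hospital alphabetical — then
standardises every column. Encoding hospital as an ordinal makes it a
pseudo-continuous coordinate; that is a quirk of the integer-conversion
procedure being reproduced, and is acknowledged rather than repaired.
Records whose BMI would have required imputation are excluded — matching
must not happen on invented values. `nearest_match()` then selects, per
`R_BP` case and per candidate group, the pool member at minimum Euclidean
distance, with replacement across cases (no iterative rebalancing), ties
broken deterministically by identifier ordinal, and the final per-group
matched sets deduplicated — which is why the matched sets can be smaller
than the case count.

## The synthetic cohort generator

`generate_cohort()` produces clinical records, an LC-MS run, a count table
with a phylogeny, and the ground truth, from one seeded configuration
(`sim_config()`). Its defaults *are* the study conditions of the reference
cohort: n = 419 with group fractions 45.6 / 50.6 / 3.8% (which apportion to
exactly 191 / 212 / 16), 20 hospitals, and covariate moments taken from the
printed cohort table (age 63.4 +- 10.3, BMI 28.1 +- 6.1, per-group
medication rates, and so on). Hospital ULNs are drawn from {104, 115, 130}
U/L — the reference only states that ULN depends on each hospital's assay
kit, so plausible UK laboratory values are used.

ALP values are constructed so that `classify_response()` recovers the
planted label exactly, with safety margins off every decision boundary;
skewed labs (bilirubin, ALT) are log-normal with matching moments. The
LC-MS run uses log-normal intensities, per-group effects planted on the
log scale (defaults |beta| = 0.1-0.3, positive in `R` and negative in
`R_BP`, mirroring the reported fecal bile-acid pattern; these are plausible
mimics, not calibrated fits, since the reference reports only regression
coefficients), a pooled-QC mean profile, and a smooth multiplicative drift
g(u) = 1 + A q(u) with q a cubic in normalised run order scaled to max
|q| = 1 — smooth, loess-recoverable, and with `drift_amplitude` the exact
fractional amplitude. Censoring below a per-feature LOD quantile yields
missing-not-at-random gaps at a configurable rate (default 5%).

Counts come from a log-normal-Poisson model — chosen over
Dirichlet-multinomial because it gives direct control of per-taxon
log-fold-changes on the same scale as the clr linear analysis — with
heavy-tailed taxon base abundances (SD 3 on the log scale), log-normal
library sizes, unit log-normal cell overdispersion, planted log-fold
changes, and optional structural zeros. A global scaling factor is solved
numerically so the expected zero fraction matches the `sparsity` setting.
The default sparsity 0.980 was fixed by a one-time calibration so that
~4.5% of 9,865 taxa pass the 10% prevalence filter, reproducing the
reference regime of 447 prevalent taxa out of 9,865 (seeds 1/2/42 give
4.5-4.8%). The tree is a random bifurcation with exponential branch
lengths.

What the generator does *not* emulate: real taxon co-occurrence and
phylogenetic signal in abundances, batch-to-batch sequencing effects,
retention-time drift or adduct structure in LC-MS, and any real coupling
between clinical covariates and omics beyond the planted group effects.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under a realistic marginal structure — not that the
biological effect sizes of any particular cohort would be recovered.

## Numerical choices and degenerate inputs

* Fisher tie tolerance: relative 1e-7; probabilities compared in log space.
* PERMANOVA: perfect separation yields an infinite pseudo-F, handled so the
  permutation p-value remains exact; permutation comparisons use a relative
  1e-12 guard against float ties.
* Mixed models: singular fits are valid; `lrt_response()` errors if the
  full model's likelihood falls below the null's beyond tolerance (a refit
  signal), and clips small negative Lambda to zero.
* Zero-variance columns: an error in matching covariates (a constant
  cannot be standardised), a warning-and-skip in the correlation screen.
* Degenerate tests: both-groups-constant t-test returns p = 1 when means
  agree and errors otherwise; all-tied Kruskal-Wallis returns H = 0
  without a division blow-up; one-level categorical table rows are emitted
  with the test marked inapplicable.
* All randomness flows through explicit seeds; every seeded routine
  restores the caller's RNG state.

## Problem sizes

The bundled tests run the complete pipeline at the default study scale
(419 patients, 9,865 taxa, 999 permutations) — about a minute on one core —
and use reduced scales (100-200 patients, a few hundred taxa) for
property-style checks, with calibration suites of 600 null features and
200 recovery replicates. These sizes were chosen to make the binomial
tolerance bands tight enough to be informative while keeping the default
`R CMD check` experience fast.

## Known limitations

* `da_clr_lm()` is not a reimplementation of bias-corrected DA estimators;
  its results on real data will differ from tools that estimate sampling
  fractions.
* The exact Fisher enumeration is practical for the table shapes of cohort
  characteristics tables (free-cell count up to ~6 with one small margin);
  larger tables hit the budget error and should use Monte-Carlo.
* The QRILC-style imputation assumes per-feature log-normality of the
  censored tail; heavy-tailed features will have their tails understated.
* Faith's PD requires every observed taxon to be a tip; there is no
  fuzzy matching of taxon identifiers.
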