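# udcaresponse

Stratified analysis of the dynamic response to ursodeoxycholic acid (UDCA)
in primary biliary cholangitis (PBC), from liver biochemistry down to gut
microbiome and bile-acid profiles.

PBC patients on UDCA are classified by the Barcelona dynamic criterion:
a patient responds (`R`) when alkaline phosphatase (ALP) falls by more than
40% of the pre-treatment value or normalises (ALP_post ≤ ULN, the
hospital-specific upper limit of normal). Responders whose ALP nevertheless
remains above the Toronto/POISE bad-prognosis threshold,

    R_BP:  ALP_post > 1.67 × ULN   (within R),

form a small paradoxical subgroup with distinct liver biochemistry, fecal
bile-acid and microbial profiles. The package implements the complete
analysis battery used to characterise these groups, for statisticians and
computational biologists working with multi-omics PBC (or similar
cholestatic-disease) cohorts:

* **Response classification** — `classify_response()`, `tukey_outlier_fence()`,
  clinical covariate imputation (`impute_clinical()`).
* **Cohort table statistics** — an exact r×c Fisher test by
  margin-constrained enumeration (`fisher_exact_rxc()`), one-way ANOVA from
  raw data *or* printed summary statistics (`oneway_anova()`),
  Kruskal–Wallis, Welch/Student t, all assembled by `build_table_one()`.
* **LC-MS preprocessing** — QC-anchored loess drift correction, two-stage
  detection-limit/CV filtering, fecal-mass normalisation, bile-acid family
  sums, log transform with seeded left-censored (QRILC-style) imputation
  (`preprocess_ms()`); PQN normalisation and peak AUC for NMR.
* **Compositional 16S statistics** — prevalence filtering, geometric
  Bayesian-multiplicative zero replacement, centred log-ratio transform,
  alpha diversity including Faith's PD, clr-PCA beta-diversity
  (`process_microbiome()`).
* **Variance partitioning** — marginal PERMANOVA (each factor the only
  predictor) with Gower centring, seeded/exhaustive permutation p-values and
  BH adjustment (`variance_table()`).
* **Association testing** — per-feature mixed models with a hospital random
  intercept and likelihood-ratio inference (`test_features_lmm()`), a
  transparent clr-linear-model stand-in for matched-subset differential
  abundance (`da_clr_lm()`), structural-zero false-positive-rate curves
  (`structural_zero_fpr()`), and a taxa–metabolite Pearson screen with
  |r| ≥ 0.2 at 10% FDR (`correlation_screen()`).
* **Confounder matching** — integer-encoded, standardised nearest-neighbour
  matching of `R_BP` cases to `NR`/`R` controls (`match_rbp_subset()`).
* **Synthetic cohorts** — `generate_cohort()` builds clinical + LC-MS +
  microbiome data with known planted labels and effect sizes; its defaults
  emulate a 419-patient, 20-hospital reference cohort (group sizes
  191/212/16, ~4.5% of 9,865 taxa prevalent at 10%).

`run_pipeline()` chains every stage and writes per-stage TSVs plus a JSON
manifest that reproduces the run byte-for-byte.

## Worked example

```r
library(udcaresponse)

classify_response(c(300, 600, 200), c(120, 350, 160), uln_alp = 130)
#> [1] R    R_BP NR
#> Levels: NR R R_BP

# exact Fisher test on a printed 2x3 cohort table (celiac disease by group)
fisher_exact_rxc(rbind(yes = c(4, 2, 2), no = c(187, 210, 14)))
#> fisher_exact_rxc
#>   p = 0.02512

# one-way ANOVA directly from printed per-group summaries (age)
oneway_anova(data.frame(n = c(191, 212, 16),
                        mean = c(61.97, 64.47, 66.81),
                        sd = c(10.69, 9.99, 7.70)))
#> oneway_anova
#>   statistic = 3.9027 (df =   2, 416)
#>   p = 0.02093

# a synthetic cohort, end to end
cfg <- sim_config(n_patients = 150, n_hospitals = 6, n_taxa = 500,
                  n_features_ms = 30, n_qc = 12, sparsity = 0.9, seed = 42)
bundle <- generate_cohort(cfg)
res <- run_pipeline(bundle, n_perm = 199, seed = 42)

table(res$labels)                       # recovered planted groups
#>   NR    R R_BP
#>   68   76    6

head(res$permanova_taxa[order(res$permanova_taxa$p_adjusted),
     c("factor", "r_squared", "pseudo_f", "p_value", "p_adjusted")], 3)
#>        factor   r_squared pseudo_f p_value p_adjusted
#> 1    response 0.017701744 1.324525   0.010     0.0675
#> 5 antibiotics 0.008816480 1.316445   0.015     0.0675
#> 2         sex 0.007118819 1.061139   0.285     0.5130

subset(res$association_ms, significant,
       select = c(feature, beta_R, beta_R_BP, p_value, p_adjusted))[1:4, ]
#>   feature    beta_R  beta_R_BP      p_value  p_adjusted
#> 1   BA001 0.1207088 -0.3884957 0.0328766658 0.078538702
#> 3   BA003 0.2258547 -0.2099102 0.0077257077 0.023728959
#> 5   BA005 0.2830959 -0.3936157 0.0011321523 0.005409172
#> 6   BA006 0.2485656 -0.3929197 0.0004628283 0.002487702
```

The Fisher p-value (0.025) and ANOVA p-value (0.021) reproduce the printed
reference-cohort values for those rows; the planted group labels come back
exactly; the LC-MS features carrying planted log-scale effects (positive in
`R`, negative in `R_BP`) are flagged at 10% FDR with signed coefficient
estimates close to truth.

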