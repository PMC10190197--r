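# Small in-code fixtures shared across test files.

# minimal feature run: `values` is a samples x features intensity matrix,
# QC rows flagged by `qc`
make_run <- function(values, qc = rep(FALSE, nrow(values)),
                     run_order = seq_len(nrow(values)),
                     fecal_mass = rep(100, nrow(values)),
                     matrix_type = "fecal", lod = NULL) {
  n <- nrow(values)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    run_order = run_order,
    role = ifelse(qc, "QC", "study"),
    fecal_mass = ifelse(qc, NA_real_, fecal_mass))
  rownames(values) <- samples$sample_id
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("F%03d", seq_len(ncol(values)))
  feature_run(samples = samples, intensities = values, lod = lod,
              matrix_type = matrix_type)
}

# small, fast cohort configuration for pipeline-level tests
small_config <- function(seed = 1, ...) {
  sim_config(n_patients = 100, n_hospitals = 5, n_taxa = 300,
             n_features_ms = 24, n_qc = 10, sparsity = 0.9,
             effect_sizes_ms = data.frame(feature = 1:4, beta_R = 0.3,
                                          beta_R_BP = -0.3),
             effect_sizes_taxa = data.frame(taxon = 1:3, beta_R = 0.8,
                                            beta_R_BP = -1),
             seed = seed, ...)
}

# naive Fisher oracle: enumerate every margin-consistent table by brute
# force over all free cells (no pruning, no sorting) and sum probabilities
# not exceeding the observed one
fisher_brute_force <- function(tab, tol = 1e-7) {
  rs <- rowSums(tab); cs <- colSums(tab)
  R <- nrow(tab); C <- ncol(tab)
  logK <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(tab) + 1)
  free <- expand.grid(rep(list(0:max(sum(tab))), (R - 1) * (C - 1)))
  logp_obs <- logK - sum(lgamma(tab + 1))
  total <- 0
  for (k in seq_len(nrow(free))) {
    m <- matrix(0, R, C)
    m[seq_len(R - 1), seq_len(C - 1)] <- as.numeric(free[k, ])
    m[seq_len(R - 1), C] <- rs[seq_len(R - 1)] - rowSums(m[seq_len(R - 1), , drop = FALSE])
    m[R, ] <- cs - colSums(m)
    if (any(m < 0)) next
    logp <- logK - sum(lgamma(m + 1))
    if (logp <= logp_obs + log1p(tol)) total <- total + exp(logp)
  }
  min(total, 1)
}

# independent PERMANOVA oracle from the pairwise-distance identity:
# SS_total = sum_{i<j} d_ij^2 / n, SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g
permanova_f_oracle <- function(d, f) {
  d <- as.matrix(d); n <- nrow(d)
  f <- factor(f)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in levels(f)) {
    idx <- which(f == g)
    dg <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  df1 <- nlevels(f) - 1; df2 <- n - nlevels(f)
  list(f = (ss_between / df1) / (ss_within / df2),
       r2 = ss_between / ss_total)
}
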