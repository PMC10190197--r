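test_that("p-value adjustment reproduces the closed-form BH and Holm cases", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "Holm"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(0.3, "BH"), 0.3)
  # never decreases, order preserved, NA pass-through
  set.seed(2)
  p <- runif(20)
  expect_true(all(adjust_pvalues(p, "BH") >= p))
  # monotone in the input magnitudes (ties allowed), order preserved
  expect_true(all(diff(adjust_pvalues(p, "BH")[order(p)]) >= 0))
  expect_true(is.na(adjust_pvalues(c(0.5, NA), "BH")[2]))
  expect_error(adjust_pvalues(numeric(0)), "empty")
  expect_error(adjust_pvalues(c(0.5, 0)), "0, 1")
})

test_that("mixed-model fit degenerates to OLS when there is no hospital effect", {
  set.seed(51)
  n <- 120
  design <- data.frame(response = factor(rep(c("NR", "R", "R_BP"), n / 3)),
                       age = rnorm(n))
  hosp <- factor(rep(sprintf("H%d", 1:6), each = n / 6))
  y <- 0.5 * (design$response == "R") + 0.2 * scale(design$age)[, 1] +
    rnorm(n, 0, 1)   # tau2 = 0 truth
  fit <- fit_feature_lmm(y, design, hosp)
  expect_true(fit$converged || fit$tau2 < 1e-6)
  ols <- lm(y ~ response + scale(age), data = design)
  expect_lt(fit$tau2, 0.05)
  expect_equal(fit$coefficients$estimate,
               unname(coef(ols)), tolerance = 0.02)

  # single hospital falls back to a flagged plain linear model
  fit1 <- fit_feature_lmm(y, design, factor(rep("H1", n)))
  expect_equal(fit1$model, "lm")
  expect_equal(fit1$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-10)
})

test_that("balanced within-hospital-centred covariate reproduces the GLS closed form", {
  # when the covariate is centred within each hospital, x is orthogonal to
  # the random-intercept design, so the GLS slope equals the OLS slope for
  # ANY variance ratio -- the mixed model must reproduce it exactly
  set.seed(52)
  n_h <- 8; m <- 10
  hosp <- factor(rep(sprintf("H%d", 1:n_h), each = m))
  x <- rep(seq(-1, 1, length.out = m), n_h)        # identical per hospital
  b_h <- rnorm(n_h, 0, 2)[as.integer(hosp)]
  y <- 1.5 * x + b_h + rnorm(n_h * m, 0, 0.5)
  fit <- fit_feature_lmm(y, data.frame(x = x), hosp, scale_covariates = FALSE)
  beta_gls <- sum(x * y) / sum(x * x)              # hand-derived closed form
  expect_true(fit$converged)
  expect_equal(fit$coefficients$estimate[2], beta_gls, tolerance = 1e-6)
  expect_gt(fit$tau2, 0.5)                         # hospital variance found
})

test_that("likelihood-ratio test handles identity, nesting and inference", {
  set.seed(53)
  n <- 90
  design <- data.frame(response = factor(rep(c("NR", "R", "R_BP"), n / 3)),
                       age = rnorm(n))
  hosp <- factor(rep(sprintf("H%d", 1:6), length.out = n))
  y <- rnorm(n) + 0.8 * (design$response == "R_BP")
  full <- fit_feature_lmm(y, design, hosp)
  null <- fit_feature_lmm(y, design["age"], hosp)

  # identical models: lambda = 0, p = 1
  same <- lrt_response(full, full, df = 2)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  res <- lrt_response(full, null)
  expect_equal(res$df, 2)   # two response dummy columns
  expect_gt(res$statistic, 0)
  expect_lt(res$p_value, 0.05)
  # chi-square reference
  expect_equal(res$p_value, pchisq(res$statistic, 2, lower.tail = FALSE))
  # reversed nesting must error
  expect_error(lrt_response(null, full), "nested|refit")
})

test_that("LRT statistic is invariant to affine rescaling of covariates", {
  set.seed(54)
  n <- 80
  design <- data.frame(response = factor(rep(c("NR", "R"), n / 2)),
                       age = rnorm(n, 60, 10), bmi = rnorm(n, 28, 5))
  hosp <- factor(rep(sprintf("H%d", 1:4), length.out = n))
  y <- rnorm(n) + 0.5 * (design$response == "R") + 0.01 * design$age
  res1 <- test_features_lmm(matrix(y), design$response,
                            design[c("age", "bmi")], hosp)
  design2 <- design
  design2$age <- design$age * 3 + 100   # affine rescale
  res2 <- test_features_lmm(matrix(y), design2$response,
                            design2[c("age", "bmi")], hosp)
  expect_equal(res1$statistic, res2$statistic, tolerance = 1e-6)
})

test_that("planted metabolome effects are detected downstream at 10% FDR", {
  # generator default beta = 0.3 at ~100 samples/group: the full
  # generate -> preprocess -> mixed-model-LRT chain must flag the planted
  # feature in most seeds
  hits <- sapply(1:12, function(s) {
    cfg <- sim_config(n_patients = 200,
                      group_fractions = c(0.5, 0.5, 0),
                      n_hospitals = 5, n_features_ms = 12, n_qc = 10,
                      censor_fraction = 0.02,
                      effect_sizes_ms = data.frame(feature = 1,
                                                   beta_R = 0.3,
                                                   beta_R_BP = 0),
                      n_taxa = 50, sparsity = 0.7, seed = 6000 + s)
    rec <- generate_clinical(cfg)
    run <- generate_metabolome(cfg, rec)
    pp <- preprocess_ms(run, seed = s, families = FALSE)
    study <- pp$run$samples$role == "study"
    m <- pp$run$intensities[study, , drop = FALSE]
    idx <- match(pp$run$samples$sample_id[study], rec$patient_id)
    res <- test_features_lmm(m, attr(rec, "labels")[idx], NULL,
                             rec$hospital[idx], fdr = 0.1)
    isTRUE(res$significant[res$feature == "BA001"])
  })
  expect_gte(mean(hits), 0.8)
})

test_that("matched-subset clr differential abundance flags planted shifts", {
  set.seed(61)
  n <- 45
  g <- factor(rep(c("NR", "R", "R_BP"), each = 15))
  lam <- matrix(rep(c(50, 30, 20, 10, 5, 40, 25, 15, 8, 60), each = n),
                n, 10)
  lam[g == "R_BP", 3] <- lam[g == "R_BP", 3] * exp(1.5)  # planted shift
  m <- matrix(rpois(n * 10, lam), n, 10)
  m[rowSums(m) == 0, 1] <- 1L
  tbl <- count_table(m)
  design <- data.frame(response = g, age = rnorm(n, 60, 8),
                       bmi = rnorm(n, 28, 4))
  res <- da_clr_lm(tbl, design)
  expect_true(res$significant[3])
  expect_match(attr(res, "method"), "stand-in")

  # taxon order permutation permutes results identically
  perm <- sample(10)
  res_p <- da_clr_lm(count_table(m[, perm]), design)
  expect_equal(res_p$p_value, res$p_value[perm], tolerance = 1e-10)

  # compositional closure: scaling one sample's counts changes nothing
  m2 <- m; m2[5, ] <- m2[5, ] * 7L
  res_s <- da_clr_lm(count_table(m2), design)
  expect_equal(res_s$p_value, res$p_value, tolerance = 1e-9)

  expect_error(da_clr_lm(tbl, data.frame(response = factor(
    rep(c("NR", "R"), c(43, 2))), age = rnorm(45), bmi = rnorm(45))),
    "3 samples")
})

test_that("structural-zero FPR matches the two-group Bernoulli closed form", {
  pi <- 0.15
  for (n in c(10, 50)) {
    sim <- structural_zero_fpr(pi, n, n_groups = 2, n_sim = 20000, seed = 4)
    q <- (1 - pi)^n
    analytic <- 2 * q * (1 - q)
    expect_lt(abs(sim$fpr - analytic), 3 * max(sim$se, 1e-4))
  }
  # monotone decreasing in per-group n; vanishing for pi -> 1
  f10 <- structural_zero_fpr(0.05, 10, n_sim = 20000, seed = 9)$fpr
  f50 <- structural_zero_fpr(0.05, 50, n_sim = 20000, seed = 9)$fpr
  expect_gt(f10, f50)
  expect_lt(structural_zero_fpr(0.999, 20, n_sim = 1000, seed = 2)$fpr, 0.01)
  expect_error(structural_zero_fpr(1.2, 10), "pi")
  expect_error(structural_zero_fpr(0.5, 10, n_sim = 50), "n_sim")
})

test_that("correlation screen recovers planted pairs and applies both filters", {
  set.seed(71)
  n <- 60
  taxa <- matrix(rnorm(n * 5), n, 5,
                 dimnames = list(NULL, paste0("T", 1:5)))
  mets <- matrix(rnorm(n * 4), n, 4,
                 dimnames = list(NULL, paste0("M", 1:4)))
  mets[, 2] <- 0.6 * taxa[, 3] + sqrt(1 - 0.36) * rnorm(n)  # planted r ~ 0.6
  res <- correlation_screen(taxa, mets)
  hit <- res[res$taxon == "T3" & res$metabolite == "M2", ]
  expect_true(hit$reported)
  expect_gt(hit$r, 0.3)

  # a column against itself is a perfect reported correlation
  self <- correlation_screen(taxa[, 1, drop = FALSE],
                             cbind(S = taxa[, 1]))
  expect_equal(self$r, 1)
  expect_true(self$reported)

  # zero-variance columns are skipped with a warning
  taxa0 <- cbind(taxa, flat = 1)
  expect_warning(res0 <- correlation_screen(taxa0, mets), "flat")
  expect_false("flat" %in% res0$taxon)

  # the reported flag requires BOTH adjusted significance and |r| >= 0.2
  expect_true(all(abs(res$r[res$reported]) >= 0.2))
  expect_true(all(res$p_adjusted[res$reported] < 0.1))
})
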