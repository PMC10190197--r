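test_that("drift correction is identity for flat QCs and recovers shared drift", {
  set.seed(21)
  n <- 40
  qc <- seq_len(n) %% 5 == 1
  base <- matrix(rep(c(1000, 2000, 500), each = n), n, 3)

  # constant QC TIC: smooth/mean = 1 everywhere
  out <- drift_correct_loess(make_run(base, qc = qc))
  expect_equal(out$intensities, make_run(base, qc = qc)$intensities,
               tolerance = 1e-10)

  # shared linear decay applied to everyone, QCs included
  g <- seq(1.3, 0.7, length.out = n)
  drifted <- base * g
  corr <- drift_correct_loess(make_run(drifted, qc = qc))
  cv <- apply(corr$intensities, 2, sd) / colMeans(corr$intensities)
  expect_true(all(cv < 0.01))

  # scale equivariance: global rescaling passes through the mean-1 smooth
  corr10 <- drift_correct_loess(make_run(drifted * 10, qc = qc))
  expect_equal(corr10$intensities, corr$intensities * 10, tolerance = 1e-9)

  # a study-only perturbation leaves other samples untouched
  pert <- drifted
  pert[3, ] <- pert[3, ] * 5   # sample 3 is a study sample
  corr_p <- drift_correct_loess(make_run(pert, qc = qc))
  expect_equal(corr_p$intensities[-3, ], corr$intensities[-3, ],
               tolerance = 1e-12)

  expect_error(drift_correct_loess(make_run(base, qc = qc), span = 0),
               "span")
  expect_error(drift_correct_loess(make_run(base * 0, qc = qc)), "zero")
  expect_error(drift_correct_loess(make_run(base)), "QC")
})

test_that("feature filters discard by QC LOD, QC CV and study LOD with reasons", {
  set.seed(5)
  n <- 30; qc <- seq_len(n) %% 3 == 1   # 10 QCs
  x <- matrix(rlnorm(n * 4, log(1000), 0.05), n, 4)
  x[qc, 2] <- runif(sum(qc), 0, 1)            # feature 2: below LOD in QCs
  x[qc, 3] <- rlnorm(sum(qc), log(1000), 0.6) # feature 3: QC CV way over 30%
  x[!qc, 4] <- c(runif(15, 0, 1), rlnorm(5, log(1000), 0.05)) # study LOD 75%
  run <- make_run(x, qc = qc, lod = rep(10, 4))

  res <- apply_feature_filters(run)
  expect_equal(res$stats$reason, c("", "qc_lod", "qc_cv", "study_lod"))
  expect_equal(colnames(res$run$intensities), "F001")
  expect_equal(nrow(res$stats), 4)   # stats retained for dropped features too
  expect_true(all(res$stats$frac_below_lod_qc >= 0 &
                  res$stats$frac_below_lod_qc <= 1))
})

test_that("fecal-mass normalisation rescales study samples only", {
  x <- matrix(rep(c(100, 200), each = 6), 6, 2)
  run <- make_run(x, qc = c(TRUE, rep(FALSE, 4), TRUE),
                  fecal_mass = c(NA, 50, 100, 100, 25, NA))
  out <- normalize_fecal_mass(run)
  expect_equal(out$intensities[2, 1], 2)            # 100 / 50
  expect_equal(out$intensities[5, 1], 4)            # 100 / 25
  expect_equal(out$intensities[1, ], run$intensities[1, ])  # QC untouched

  # doubling one sample's mass halves its values
  run2 <- run; run2$samples$fecal_mass[2] <- 100
  expect_equal(normalize_fecal_mass(run2)$intensities[2, ],
               out$intensities[2, ] / 2)

  # unit mass is the identity; serum matrices pass through
  run3 <- make_run(x, fecal_mass = rep(1, 6))
  expect_equal(normalize_fecal_mass(run3)$intensities, run3$intensities)
  run4 <- make_run(x, matrix_type = "serum")
  expect_identical(normalize_fecal_mass(run4), run4)

  run$samples$fecal_mass[2] <- NA
  expect_error(normalize_fecal_mass(run), "fecal_mass")
})

test_that("log-impute-centre: exact on complete data, truncated draws otherwise", {
  set.seed(77)
  x <- matrix(rlnorm(60, 8, 0.4), 20, 3)
  run <- make_run(x)
  out <- log_impute_center(run)
  expect_equal(unname(colMeans(out$intensities)), rep(0, 3), tolerance = 1e-12)
  expect_equal(out$intensities,
               scale(log(run$intensities), scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)

  # censored entries are imputed strictly below the observed minimum
  # (centring subtracts the same constant from every entry of a column, so
  # the ordering can be asserted on the centred scale)
  xc <- x
  xc[x[, 2] < quantile(x[, 2], 0.25), 2] <- NA
  outc <- log_impute_center(make_run(xc), seed = 3)
  imp <- attr(outc, "imputed")[, 2]
  expect_true(any(imp))
  expect_lt(max(outc$intensities[imp, 2]), min(outc$intensities[!imp, 2]))

  # determinism under seed
  outc2 <- log_impute_center(make_run(xc), seed = 3)
  expect_identical(outc$intensities, outc2$intensities)

  xc[, 3] <- NA; xc[1:2, 3] <- c(100, 200)
  expect_error(log_impute_center(make_run(xc)), "fewer than 3")
})

test_that("imputed values track the true censored tail of an MNAR normal", {
  # generating truth: N(5, 1) log-intensities censored below the 20% quantile
  mu <- 5; sd_ <- 1; cf <- 0.2
  q <- qnorm(cf, mu, sd_)
  tail_mean_true <- mu - sd_ * dnorm((q - mu) / sd_) / pnorm((q - mu) / sd_)
  errs <- sapply(1:100, function(s) {
    set.seed(1000 + s)
    lx <- rnorm(150, mu, sd_)
    x <- exp(lx)
    x[lx < q] <- NA
    out <- log_impute_center(make_run(cbind(x, rlnorm(150, 5, 1))), seed = s)
    imp <- attr(out, "imputed")[, 1]
    # recover the column mean the centring removed from the observed cells,
    # then reconstruct the raw-log-scale imputed values
    col_mean <- (log(x[!imp]) - out$intensities[!imp, 1])[1]
    mean(out$intensities[imp, 1] + col_mean) - tail_mean_true
  })
  expect_lt(abs(mean(errs)), 0.5 * sd_)
})

test_that("PQN recovers dilution factors and is idempotent", {
  set.seed(12)
  ref <- rlnorm(200, 3, 0.8)
  dil <- c(1, 0.5, 2, 1.5, 0.8)
  spectra <- outer(dil, ref)

  res <- pqn_normalize(spectra)
  # exact proportional spectra: dilutions recovered up to the cohort median
  expect_equal(res$dilution / median(res$dilution), dil / median(dil),
               tolerance = 1e-12)
  expect_true(all(apply(res$normalized, 2, function(v) diff(range(v))) < 1e-9))

  # the reference spectrum itself has dilution 1
  expect_equal(unname(pqn_normalize(rbind(ref, ref, 2 * ref))$dilution[1]), 1)

  # multiplicative noise sigma = 0.05: dilutions within 2% of truth
  noisy <- spectra * matrix(exp(rnorm(length(spectra), 0, 0.05)),
                            nrow(spectra))
  res_n <- pqn_normalize(noisy)
  rel <- (res_n$dilution / median(res_n$dilution)) / (dil / median(dil))
  expect_true(all(abs(rel - 1) < 0.02))

  # idempotence on already-normalised data
  again <- pqn_normalize(res$normalized)
  expect_equal(unname(again$dilution), rep(1, 5), tolerance = 1e-12)

  expect_error(pqn_normalize(matrix(1:4, 1)), "2 samples")
  bad <- spectra; bad[, 1] <- 0
  expect_error(pqn_normalize(bad), "non-positive")
})

test_that("peak AUC matches rectangle, triangle and Gaussian closed forms", {
  ppm <- seq(0, 1, by = 0.001)
  rect <- as.numeric(ppm >= 0.4 & ppm <= 0.5)
  expect_equal(peak_auc(ppm, rect, c(0.4, 0.5)), 0.1, tolerance = 1e-6)

  tri <- pmax(0, 1 - abs(ppm - 0.5) / 0.1)    # base 0.2, height 1
  expect_equal(peak_auc(ppm, tri, c(0.3, 0.7)), 0.5 * 0.2 * 1,
               tolerance = 1e-4)

  # fine-grid Gaussian vs analytic integral
  ppm_f <- seq(0, 2, by = 5e-4)
  gauss <- dnorm(ppm_f, 1, 0.05)
  win <- c(0.9, 1.1)
  analytic <- pnorm(1.1, 1, 0.05) - pnorm(0.9, 1, 0.05)
  expect_equal(peak_auc(ppm_f, gauss, win), analytic, tolerance = 1e-3)

  expect_error(peak_auc(ppm, rect, c(1.5, 1.6)), "outside")
})

test_that("bile-acid family sums are permutation-invariant partitions", {
  set.seed(3)
  x <- matrix(rlnorm(40, 6, 0.5), 5, 8)
  colnames(x) <- sprintf("BA%03d", 1:8)
  run <- make_run(x)
  run$features <- data.frame(
    feature_id = colnames(x),
    ba = rep(c("CA", "DCA"), each = 4),
    conjugation = rep(c("unconjugated", "glyco", "tauro", "glyco"), 2))

  fam <- compute_ba_families(run)
  m <- fam$intensities
  expect_equal(unname(m[, "G-BAs"]), unname(rowSums(x[, c(2, 4, 6, 8)])))
  expect_equal(unname(m[, "T-BAs"]), unname(rowSums(x[, c(3, 7)])))
  expect_equal(m[, "CA_total"] + m[, "DCA_total"], m[, "total_BA"])
  expect_equal(unname(m[, "total_BA"]), unname(rowSums(x)))

  # permuting feature order leaves the sums unchanged
  perm <- sample(8)
  run_p <- run
  run_p$intensities <- run$intensities[, perm]
  run_p$features <- run$features[perm, ]
  fam_p <- compute_ba_families(run_p)
  expect_equal(fam_p$intensities[, "G-BAs"], m[, "G-BAs"])

  # one-member family equals its member
  one <- compute_ba_families(run, data.frame(feature_id = "BA001",
                                             family = "solo"))
  expect_equal(unname(one$intensities[, "solo"]), unname(x[, 1]))

  expect_error(compute_ba_families(run, data.frame(feature_id = "nope",
                                                   family = "bad")),
               "bad")
})

test_that("the preprocessing chain enforces its stage order", {
  cfg <- small_config(seed = 6)
  rec <- generate_clinical(cfg)
  run <- generate_metabolome(cfg, rec)
  res <- preprocess_ms(run, seed = 2)
  expect_true(res$run$log_scale)
  expect_equal(unname(colMeans(res$run$intensities)),
               rep(0, ncol(res$run$intensities)), tolerance = 1e-10)
  # family sums computed on the intensity scale only
  expect_error(compute_ba_families(res$run), "intensity scale")
  expect_error(log_impute_center(res$run), "already")
})
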