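test_that("response classification follows the dynamic and bad-prognosis rules", {
  # normalised ALP -> R even without a 40% fall
  expect_equal(as.character(classify_response(300, 120, 130)), "R")
  # 41.7% fall but ALP still above 1.67 x ULN -> R_BP
  expect_equal(as.character(classify_response(600, 350, 130)), "R_BP")
  # 20% fall, still elevated -> NR
  expect_equal(as.character(classify_response(200, 160, 130)), "NR")
  # boundary: exactly 40% fall is NOT a response; exactly at ULN is
  expect_equal(as.character(classify_response(200, 120, 100)), "NR")
  expect_equal(as.character(classify_response(200, 100, 100)), "R")
  # exactly 1.67 x ULN stays R (rule is strictly greater)
  expect_equal(as.character(classify_response(1000, 167, 100)), "R")

  labs <- classify_response(c(300, 600, 200), c(120, 350, 160), 130)
  expect_s3_class(labs, "factor")
  expect_identical(levels(labs), c("NR", "R", "R_BP"))

  expect_error(classify_response(-1, 100, 100), "alp_pre")
  expect_error(classify_response(100, NA, 100), "alp_post")
  expect_error(classify_response(data.frame(alp_pre = 1, alp_post = 1)),
               "uln_alp")
})

test_that("Tukey upper fence flags only values above Q3 + 1.5 IQR", {
  expect_error(tukey_outlier_fence(c(1, 2, 3)), "4")
  # all equal -> nothing flagged
  expect_false(any(tukey_outlier_fence(rep(5, 10))))
  # hand-computed type-7 oracle: Q1 = 3, Q3 = 7, fence = 13
  flags <- tukey_outlier_fence(c(1:8, 100))
  expect_equal(which(flags), 9L)
  expect_equal(attr(flags, "fence"), 13)

  # with a uniform ULN, synthetic R-group ALP built with 1.67 x ULN
  # exceedances is flagged exactly at the bad-prognosis threshold
  set.seed(4)
  uln <- 115
  alp <- c(runif(120, 0.4, 1.1) * uln, runif(6, 1.9, 2.6) * uln)
  expect_equal(unname(which(tukey_outlier_fence(alp))),
               unname(which(alp > 1.67 * uln)))
})

test_that("clinical imputation uses mode, weight regression, then sex medians", {
  rec <- data.frame(
    patient_id = sprintf("P%02d", 1:9),
    sex = factor(rep(c("female", "male"), c(6, 3))),
    smoking = factor(c("never", "never", "never", "former", "former", NA,
                       "never", "never", "former"),
                     levels = c("never", "former", "current")),
    weight = c(60, 70, 80, 65, NA, 75, 85, 90, 95),
    bmi = c(22, 24, 26, 23, NA, NA, 27, 28, NA))
  # make BMI exactly linear in weight within the complete records
  rec$bmi <- 0.2 * rec$weight + 10
  rec$bmi[c(5, 6, 9)] <- NA   # 5: no weight; 6, 9: weight present

  out <- impute_clinical(rec)
  expect_equal(as.character(out$smoking[6]), "never")      # modal category
  expect_equal(out$bmi[6], 0.2 * 75 + 10)                  # exact recovery
  expect_equal(out$bmi[9], 0.2 * 95 + 10)
  # both missing -> sex-specific median of observed BMI (females 1:4)
  expect_equal(out$bmi[5], median(0.2 * c(60, 70, 80, 65) + 10))
  expect_equal(attr(out, "imputed")$bmi, c(5, 6, 9))

  rec$smoking <- factor(NA, levels = "never")
  expect_error(impute_clinical(rec), "entirely missing")
})

test_that("one-way ANOVA agrees between raw data and its own summaries", {
  set.seed(11)
  gl <- list(rnorm(8, 0), rnorm(12, 0.5), rnorm(5, 1))
  raw <- oneway_anova(gl)
  summ <- oneway_anova(data.frame(n = lengths(gl),
                                  mean = sapply(gl, mean),
                                  sd = sapply(gl, sd)))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
  # matches R's own ANOVA
  y <- unlist(gl); g <- factor(rep(1:3, lengths(gl)))
  expect_equal(raw$statistic, unname(summary(aov(y ~ g))[[1]]$`F value`[1]),
               tolerance = 1e-10)

  # shift-invariance of the summary form
  shifted <- oneway_anova(data.frame(n = lengths(gl),
                                     mean = sapply(gl, mean) + 100,
                                     sd = sapply(gl, sd)))
  expect_equal(shifted$statistic, summ$statistic, tolerance = 1e-9)

  ident <- oneway_anova(data.frame(n = c(5, 5), mean = c(2, 2), sd = c(1, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(oneway_anova(data.frame(n = c(5, 1), mean = 1:2, sd = c(1, 1))))
  expect_error(oneway_anova(data.frame(n = c(5, 5), mean = 1:2, sd = c(1, -1))))
})

test_that("Kruskal-Wallis matches the hand-ranked formula and handles ties", {
  # ranks 1..6: H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(res$df, 1)

  tied <- kruskal_wallis(list(rep(2, 4), rep(2, 4)))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("two-sample t matches the closed form and degenerate conventions", {
  a <- c(5.1, 4.9, 6.2, 5.8, 5.5); b <- c(4.2, 4.8, 4.4, 5.0)
  res <- two_sample_t(a, b, "student")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(abs(t_hand), 7, lower.tail = FALSE),
               tolerance = 1e-12)

  same <- two_sample_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # equal variances and ns: Welch reduces to Student
  set.seed(2)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(two_sample_t(x, y, "welch")$statistic,
               two_sample_t(x, y, "student")$statistic, tolerance = 1e-10)

  expect_equal(two_sample_t(rep(1, 3), rep(1, 3))$p_value, 1)
  expect_error(two_sample_t(rep(1, 3), rep(2, 3)), "zero variance")
})

test_that("the cohort table summarises groups and picks the right test per row", {
  cfg <- small_config(seed = 5)
  rec <- generate_clinical(cfg)
  labs <- classify_response(rec)
  tab <- build_table_one(rec, labs)

  expect_true(all(c("variable", "level", "NR", "R", "R_BP",
                    "p_value", "method") %in% names(tab)))
  expect_equal(tab$method[tab$variable == "sex"][1], "fisher_exact_rxc")
  expect_equal(tab$method[tab$variable == "age"], "oneway_anova")
  expect_equal(tab$method[tab$variable == "udca_years"], "kruskal_wallis")

  # group Ns recoverable from any categorical row match the planted fractions
  sex_rows <- tab[tab$variable == "sex", ]
  ns <- sapply(c("NR", "R", "R_BP"), function(g)
    sum(as.numeric(sub(" .*", "", sex_rows[[g]]))))
  expect_equal(unname(ns), as.vector(table(labs)))

  # one-level categorical -> row emitted, test inapplicable
  rec$celiac <- FALSE
  tab2 <- build_table_one(rec, labs)
  crow <- tab2[tab2$variable == "celiac", ]
  expect_equal(crow$method[1], "inapplicable")
  expect_true(is.na(crow$p_value[1]))

  expect_error(build_table_one(rec, labs,
                               variables = data.frame(variable = "age",
                                                      type = "unknown")),
               "unknown variable type")
})
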