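#' Adjust p-values for multiplicity
#'
#' Benjamini-Hochberg step-up or Holm step-down adjustment (via
#' [stats::p.adjust()]); adjusted values are monotone in the input order of
#' magnitude and capped at 1, and are returned in the input order.
#'
#' @param p p-values in (0, 1].
#' @param method `"BH"` or `"Holm"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "Holm")) {
  method <- match.arg(method)
  if (!length(p)) stop("empty p-value vector")
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = if (method == "BH") "BH" else "holm")
  out
}

# scale continuous covariates to mean 0 / unit variance, leave factors alone
.scale_covariates <- function(design) {
  for (j in seq_along(design)) {
    x <- design[[j]]
    if (is.numeric(x) && stats::var(x) > 0)
      design[[j]] <- (x - mean(x)) / stats::sd(x)
  }
  design
}

#' Fit a per-feature mixed model with a hospital random intercept
#'
#' Maximum-likelihood fit (REML off, so likelihood-ratio tests on fixed
#' effects are valid) of `y ~ covariates + (1 | hospital)` via
#' [lme4::lmer()]. Continuous covariates are mean-centred and
#' univariance-scaled first. With a single hospital the model degenerates
#' and a plain linear model is fitted instead, flagged in the result.
#'
#' @param y numeric response per sample.
#' @param design data frame of fixed-effect covariates (e.g. response
#'   group, sex, age, BMI, antibiotics, PPI, smoking).
#' @param hospital grouping factor (the random intercept).
#' @param scale_covariates standardise continuous covariates (default TRUE).
#' @return object of class `lmm_fit`: `coefficients` (estimate, se, 95% CI),
#'   `sigma2`, `tau2`, `loglik_ml`, `converged`, `model` ("lmm" or "lm"),
#'   `n`.
#' @export
fit_feature_lmm <- function(y, design, hospital, scale_covariates = TRUE) {
  stopifnot(is.data.frame(design), length(y) == nrow(design),
            length(hospital) == length(y))
  hospital <- droplevels(factor(hospital))
  if (scale_covariates) design <- .scale_covariates(design)
  dat <- cbind(.y = y, design, .hospital = hospital)
  rhs <- if (ncol(design)) names(design) else "1"

  if (nlevels(hospital) < 2) {
    fit <- stats::lm(stats::reformulate(rhs, ".y"), data = dat)
    cf <- summary(fit)$coefficients
    co <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                     ci_low = cf[, 1] - 1.96 * cf[, 2],
                     ci_high = cf[, 1] + 1.96 * cf[, 2], row.names = NULL)
    return(structure(list(coefficients = co,
                          sigma2 = summary(fit)$sigma^2, tau2 = 0,
                          loglik_ml = as.numeric(stats::logLik(fit)),
                          converged = TRUE, model = "lm", n = length(y)),
                     class = "lmm_fit"))
  }

  form <- stats::as.formula(paste(
    ".y ~", paste(rhs, collapse = " + "), "+ (1 | .hospital)"))
  # boundary (singular, tau2 = 0) fits are valid ML solutions; only genuine
  # optimizer convergence failures are flagged
  converged <- TRUE
  fit <- tryCatch(
    withCallingHandlers(
      suppressMessages(lme4::lmer(form, data = dat, REML = FALSE)),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(coefficients = NULL, sigma2 = NA, tau2 = NA,
                          loglik_ml = NA_real_, converged = FALSE,
                          model = "lmm", n = length(y)), class = "lmm_fit"))
  msgs <- fit@optinfo$conv$lme4$messages
  if (length(msgs) && any(grepl("failed to converge", msgs, ignore.case = TRUE)))
    converged <- FALSE

  est <- lme4::fixef(fit)
  se <- sqrt(Matrix::diag(stats::vcov(fit)))
  vc <- lme4::VarCorr(fit)
  structure(list(
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              se = unname(se),
                              ci_low = unname(est - 1.96 * se),
                              ci_high = unname(est + 1.96 * se),
                              row.names = NULL),
    sigma2 = attr(vc, "sc")^2,
    tau2 = as.numeric(vc$.hospital[1]),
    loglik_ml = as.numeric(stats::logLik(fit)),
    converged = converged, model = "lmm", n = length(y)),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): sigma2 = %.4g, tau2 = %.4g, logLik = %.3f%s\n",
              x$model, x$n, x$sigma2, x$tau2, x$loglik_ml,
              if (!x$converged) " [NOT converged]" else ""))
  if (!is.null(x$coefficients)) print(x$coefficients, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test of nested mixed models
#'
#' Lambda = 2 (logLik_full - logLik_null), clipped at zero, referred to a
#' chi-square with `df` degrees of freedom (the number of parameters added
#' by the full model; 2 for a three-level response factor). Both fits must
#' be maximum-likelihood (not REML) on the same data.
#'
#' @param full,null [fit_feature_lmm()] fits, null nested in full.
#' @param df degrees of freedom; default inferred from the coefficient
#'   count difference.
#' @return A [test_result].
#' @export
lrt_response <- function(full, null, df = NULL) {
  stopifnot(inherits(full, "lmm_fit"), inherits(null, "lmm_fit"))
  if (!full$converged || !null$converged)
    stop("cannot form a likelihood ratio from a non-converged fit")
  if (is.null(df)) {
    if (is.null(full$coefficients) || is.null(null$coefficients))
      stop("df cannot be inferred")
    df <- nrow(full$coefficients) - nrow(null$coefficients)
  }
  if (df < 1) stop("null model must be nested in the full model")
  lambda <- 2 * (full$loglik_ml - null$loglik_ml)
  if (lambda < -1e-6 * max(1, abs(full$loglik_ml)))
    stop("full model has lower likelihood than null; refit required")
  lambda <- max(lambda, 0)
  p <- stats::pchisq(lambda, df = df, lower.tail = FALSE)
  test_result(statistic = lambda, df = df, p_value = max(p, 1e-300),
              method = "lrt_chisq")
}

#' Per-feature mixed-model association testing
#'
#' For every feature (column of `features`), fits the full model
#' `feature ~ response + covariates + (1 | hospital)` and the null model
#' without the response term, both by maximum likelihood, and tests the
#' response with a likelihood-ratio chi-square. P-values are adjusted with
#' Benjamini-Hochberg; non-converged features are reported with `NA` and
#' excluded from the adjustment family.
#'
#' @param features numeric matrix (samples x features), typically centred
#'   log intensities or clr abundances.
#' @param response factor (e.g. NR / R / R_BP), reference level first.
#' @param covariates data frame of additional fixed effects (may be empty).
#' @param hospital random-intercept grouping factor.
#' @param fdr BH significance threshold (default 0.1).
#' @return data frame per feature: response-level effects with CIs, LRT
#'   statistic, `p_value`, `p_adjusted`, `significant`, `converged`.
#' @export
test_features_lmm <- function(features, response, covariates = NULL,
                              hospital, fdr = 0.1) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("feature%03d", seq_len(ncol(features)))
  response <- droplevels(factor(response))
  if (is.null(covariates))
    covariates <- data.frame(row.names = seq_along(response))
  covariates <- .scale_covariates(covariates)
  full_design <- cbind(data.frame(response = response), covariates)

  rows <- lapply(seq_len(ncol(features)), function(j) {
    y <- features[, j]
    full <- fit_feature_lmm(y, full_design, hospital, scale_covariates = FALSE)
    null <- fit_feature_lmm(y, covariates, hospital, scale_covariates = FALSE)
    if (!full$converged || !null$converged)
      return(data.frame(feature = colnames(features)[j],
                        beta_R = NA_real_, beta_R_BP = NA_real_,
                        ci_low_R = NA_real_, ci_high_R = NA_real_,
                        ci_low_R_BP = NA_real_, ci_high_R_BP = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        converged = FALSE))
    lrt <- lrt_response(full, null, df = nlevels(response) - 1)
    co <- full$coefficients
    pick <- function(lv, col) {
      i <- match(paste0("response", lv), co$term)
      if (is.na(i)) NA_real_ else co[[col]][i]
    }
    lv2 <- levels(response)[2]
    lv3 <- if (nlevels(response) >= 3) levels(response)[3] else NA
    data.frame(feature = colnames(features)[j],
               beta_R = pick(lv2, "estimate"),
               beta_R_BP = if (is.na(lv3)) NA_real_ else pick(lv3, "estimate"),
               ci_low_R = pick(lv2, "ci_low"), ci_high_R = pick(lv2, "ci_high"),
               ci_low_R_BP = if (is.na(lv3)) NA_real_ else pick(lv3, "ci_low"),
               ci_high_R_BP = if (is.na(lv3)) NA_real_ else pick(lv3, "ci_high"),
               statistic = lrt$statistic, p_value = lrt$p_value,
               converged = TRUE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_value, "BH")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < fdr
  out
}

#' Differential abundance on a matched subset by clr linear models
#'
#' A transparent stand-in for bias-corrected compositional differential
#' abundance tools: taxa are Bayesian-multiplicative zero-replaced and
#' clr-transformed, then each taxon's clr abundance is regressed on the
#' response group plus age and BMI, with an omnibus F test for the response
#' and Holm adjustment (familywise threshold `p_threshold`). Because clr
#' coordinates are invariant to sample-wise count rescaling, results respect
#' compositional closure; no sampling-fraction bias correction is applied,
#' which is why this is labelled a stand-in in the output metadata.
#'
#' @param matched_counts [count_table] restricted to the matched subset and
#'   prevalence-filtered.
#' @param design data frame with columns `response` (factor), `age`, `bmi`.
#' @param p_threshold Holm-adjusted significance threshold (default 0.1).
#' @return data frame per taxon (effects vs reference level, F statistic,
#'   p, Holm-adjusted p, significance); `attr(, "method")` records the
#'   stand-in label.
#' @export
da_clr_lm <- function(matched_counts, design, p_threshold = 0.1) {
  stopifnot(is.data.frame(design), !is.null(design$response))
  response <- droplevels(factor(design$response))
  if (any(table(response) < 3)) stop("need at least 3 samples per group")
  clr <- clr_transform(gbm_zero_replace(matched_counts))
  covs <- .scale_covariates(design[setdiff(names(design), "response")])
  dat0 <- cbind(data.frame(response = response), covs)

  rows <- lapply(seq_len(ncol(clr)), function(j) {
    dat <- cbind(.y = clr[, j], dat0)
    full <- stats::lm(stats::reformulate(names(dat0), ".y"), data = dat)
    null <- stats::lm(stats::reformulate(
      if (length(covs)) names(covs) else "1", ".y"), data = dat)
    av <- stats::anova(null, full)
    cf <- stats::coef(full)
    lv <- levels(response)[-1]
    eff <- stats::setNames(cf[paste0("response", lv)], paste0("beta_", lv))
    data.frame(taxon = colnames(clr)[j], t(eff),
               f_statistic = av$F[2],
               p_value = max(av$`Pr(>F)`[2], 1e-300),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_value, "Holm")
  out$significant <- out$p_adjusted < p_threshold
  attr(out, "method") <- "clr-lm omnibus (stand-in; no sampling-fraction bias correction)"
  out
}

#' False-positive rate of structural-zero detection
#'
#' A structural zero is a taxon systematically absent from one group. With
#' finite samples a taxon truly present everywhere (per-sample presence
#' Bernoulli(pi) in each group) can still show an all-zero group by chance;
#' this simulation estimates that false-positive rate: the fraction of
#' simulations in which at least one group is all-zero while another has at
#' least one presence. The rate decreases monotonically in the per-group
#' sample size, which is what makes small groups unsafe for structural-zero
#' calls.
#'
#' @param pi presence probability per sample, in (0, 1).
#' @param n_per_group samples per group.
#' @param n_groups number of groups (default 3).
#' @param n_sim number of simulations (>= 100).
#' @param seed RNG seed.
#' @return list: `fpr`, Monte-Carlo `se`, `n_sim`.
#' @export
structural_zero_fpr <- function(pi, n_per_group, n_groups = 3, n_sim = 10000,
                                seed = 1L) {
  if (pi <= 0 || pi >= 1) stop("pi must lie in (0, 1)")
  if (n_sim < 100) stop("n_sim must be >= 100")
  stopifnot(n_per_group >= 1, n_groups >= 2)
  with_seed(seed, {
    pres <- matrix(stats::rbinom(n_groups * n_sim, n_per_group, pi),
                   n_groups, n_sim)
    fp <- colSums(pres == 0) > 0 & colSums(pres > 0) > 0
    fpr <- mean(fp)
    list(fpr = fpr, se = sqrt(fpr * (1 - fpr) / n_sim), n_sim = n_sim)
  })
}

#' Correlation screen between taxa and metabolites
#'
#' All pairwise Pearson correlations between two matched matrices, with
#' two-sided p-values, Benjamini-Hochberg adjustment across all pairs, and
#' a reporting flag for pairs with adjusted p below `fdr` AND |r| at or
#' above `r_threshold`. Zero-variance columns are skipped with a warning.
#'
#' @param taxa_abund numeric matrix (samples x taxa).
#' @param metabolites numeric matrix (samples x metabolites), same samples.
#' @param r_threshold minimum |r| for reporting (default 0.2).
#' @param fdr BH threshold (default 0.1).
#' @return data frame per pair: `taxon`, `metabolite`, `r`, `p_value`,
#'   `p_adjusted`, `reported`.
#' @export
correlation_screen <- function(taxa_abund, metabolites, r_threshold = 0.2,
                               fdr = 0.1) {
  x <- as.matrix(taxa_abund); y <- as.matrix(metabolites)
  stopifnot(nrow(x) == nrow(y))
  n <- nrow(x)
  if (n < 4) stop("need at least 4 matched samples")
  drop_x <- apply(x, 2, stats::var) == 0
  drop_y <- apply(y, 2, stats::var) == 0
  if (any(drop_x) || any(drop_y))
    warning("skipping zero-variance columns: ",
            paste(c(colnames(x)[drop_x], colnames(y)[drop_y]), collapse = ", "))
  x <- x[, !drop_x, drop = FALSE]; y <- y[, !drop_y, drop = FALSE]
  if (!ncol(x) || !ncol(y)) stop("no usable columns")

  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p <- pmin(pmax(p, 1e-300), 1)
  out <- data.frame(
    taxon = rep(colnames(x), times = ncol(y)),
    metabolite = rep(colnames(y), each = ncol(x)),
    r = as.vector(r), p_value = as.vector(p), stringsAsFactors = FALSE)
  out$p_adjusted <- adjust_pvalues(out$p_value, "BH")
  out$reported <- out$p_adjusted < fdr & abs(out$r) >= r_threshold
  out
}
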