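#' Classify dynamic UDCA treatment response
#'
#' Applies the Barcelona dynamic criterion and the bad-prognosis subgroup
#' rule to pre-/post-treatment alkaline phosphatase (ALP). A patient is a
#' responder (`R`) when ALP fell by more than 40% of the pre-treatment value
#' or normalised (post-treatment ALP at or below the hospital's upper limit
#' of normal, ULN). Responders whose post-treatment ALP nevertheless remains
#' above 1.67 x ULN -- the Toronto/POISE bad-prognosis threshold -- are
#' relabelled `R_BP`. Everyone else is a non-responder (`NR`).
#'
#' @param alp_pre pre-treatment ALP (U/L), or a data frame holding columns
#'   `alp_pre`, `alp_post`, `uln_alp`.
#' @param alp_post post-treatment ALP (U/L).
#' @param uln_alp hospital-specific upper limit of normal for ALP (U/L).
#'
#' @return A factor with levels `NR`, `R`, `R_BP`.
#' @examples
#' classify_response(300, 120, 130)  # normalised -> R
#' classify_response(600, 350, 130)  # >40% fall but ALP > 1.67 ULN -> R_BP
#' classify_response(200, 160, 130)  # 20% fall, still elevated -> NR
#' @export
classify_response <- function(alp_pre, alp_post = NULL, uln_alp = NULL) {
  if (is.data.frame(alp_pre)) {
    rec <- alp_pre
    for (f in c("alp_pre", "alp_post", "uln_alp"))
      if (is.null(rec[[f]])) stop_field(f, "column not found")
    alp_pre <- rec$alp_pre; alp_post <- rec$alp_post; uln_alp <- rec$uln_alp
  }
  check_positive(alp_pre, "alp_pre")
  check_positive(alp_post, "alp_post")
  check_positive(uln_alp, "uln_alp")
  n <- length(alp_pre)
  stopifnot(length(alp_post) == n, length(uln_alp) %in% c(1L, n))
  uln_alp <- rep_len(uln_alp, n)

  responder <- (1 - alp_post / alp_pre) > 0.40 | alp_post <= uln_alp
  lab <- ifelse(responder,
                ifelse(alp_post > 1.67 * uln_alp, "R_BP", "R"),
                "NR")
  factor(lab, levels = c("NR", "R", "R_BP"))
}

#' Upper Tukey outlier fence
#'
#' Flags values strictly above Q3 + 1.5 IQR (the upper whisker of a
#' box-and-whisker plot). Only the upper fence is used, matching its role in
#' identifying responders with persistently elevated ALP.
#'
#' @param values numeric vector with at least 4 finite values.
#' @param qtype quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#'
#' @return A logical vector flagging the outliers, with attribute `fence`
#'   (the numeric cut-off).
#' @export
tukey_outlier_fence <- function(values, qtype = 7) {
  v <- values[is.finite(values)]
  if (length(v) < 4) stop("need at least 4 finite values for a Tukey fence")
  q <- stats::quantile(v, c(0.25, 0.75), type = qtype, names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  out <- !is.na(values) & values > fence
  attr(out, "fence") <- fence
  out
}

#' Impute missing clinical covariates
#'
#' Categorical gaps are filled with the modal category. Missing BMI with
#' weight observed is predicted by least squares from weight and sex;
#' when weight is also missing the sex-specific median of the observed BMI
#' values is used. All other fields are left untouched.
#'
#' @param records clinical data frame; must contain `sex`, and `bmi`/`weight`
#'   when BMI imputation is needed.
#' @param categorical columns to mode-impute (defaults to every
#'   factor/character/logical column with missing entries).
#'
#' @return `records` with gaps filled. The attribute `imputed` lists, per
#'   column, the row indices that were imputed (used downstream to exclude
#'   imputed BMI from confounder matching).
#' @export
impute_clinical <- function(records, categorical = NULL) {
  stopifnot(is.data.frame(records))
  imputed <- list()

  is_cat <- vapply(records, function(x)
    is.factor(x) || is.character(x) || is.logical(x), logical(1))
  if (is.null(categorical)) categorical <- names(records)[is_cat]
  for (col in categorical) {
    x <- records[[col]]
    if (!anyNA(x)) next
    if (all(is.na(x))) stop_field(col, "entirely missing, cannot impute")
    tab <- table(x[!is.na(x)])
    mode_lvl <- names(tab)[which.max(tab)]
    idx <- which(is.na(x))
    if (is.factor(x)) x[idx] <- factor(mode_lvl, levels = levels(x))
    else if (is.logical(x)) x[idx] <- as.logical(mode_lvl)
    else x[idx] <- mode_lvl
    records[[col]] <- x
    imputed[[col]] <- idx
  }

  if (!is.null(records$bmi) && anyNA(records$bmi)) {
    if (all(is.na(records$bmi))) stop_field("bmi", "entirely missing")
    miss <- which(is.na(records$bmi))
    sex <- records$sex
    if (is.null(sex)) stop_field("sex", "required for BMI imputation")
    for (s in unique(sex[miss]))
      if (!any(!is.na(records$bmi) & sex == s))
        stop("no complete BMI record for sex level '", s, "'")
    with_weight <- miss[!is.na(records$weight[miss])]
    if (length(with_weight)) {
      cc <- !is.na(records$bmi) & !is.na(records$weight)
      fit <- stats::lm(bmi ~ weight + sex, data = records[cc, , drop = FALSE])
      records$bmi[with_weight] <-
        stats::predict(fit, newdata = records[with_weight, , drop = FALSE])
    }
    without <- setdiff(miss, with_weight)
    for (i in without)
      records$bmi[i] <- stats::median(
        records$bmi[sex == sex[i] & !seq_len(nrow(records)) %in% miss],
        na.rm = TRUE)
    imputed$bmi <- miss
  }

  attr(records, "imputed") <- imputed
  records
}

#' One-way ANOVA from raw groups or summary statistics
#'
#' Computes the classical one-way fixed-effects F test. Accepts either a
#' list of raw numeric vectors or per-group summary triples (n, mean, sd);
#' both entry points use the same between/within decomposition
#' F = \[sum n_i (m_i - m)^2 / (k-1)\] / \[sum (n_i - 1) s_i^2 / (N-k)\],
#' so summaries computed from the raw data reproduce the raw-data result to
#' machine precision. The summary form is what reproduces published cohort
#' tables where only means and SDs are printed.
#'
#' @param groups list of numeric vectors, or a data frame / matrix with
#'   columns `n`, `mean`, `sd` (one row per group).
#'
#' @return A [test_result] with `statistic` = F and `df = c(k-1, N-k)`.
#' @examples
#' oneway_anova(data.frame(n = c(191, 212, 16),
#'                         mean = c(61.97, 64.47, 66.81),
#'                         sd = c(10.69, 9.99, 7.70)))
#' @export
oneway_anova <- function(groups) {
  if (is.list(groups) && !is.data.frame(groups)) {
    if (length(groups) < 2) stop("need at least 2 groups")
    n <- lengths(groups)
    if (any(n < 2)) stop("each group needs n >= 2")
    m <- vapply(groups, mean, numeric(1))
    s <- vapply(groups, stats::sd, numeric(1))
  } else {
    groups <- as.data.frame(groups)
    if (!all(c("n", "mean", "sd") %in% names(groups)))
      stop("summary input needs columns n, mean, sd")
    n <- groups$n; m <- groups$mean; s <- groups$sd
    if (length(n) < 2) stop("need at least 2 groups")
    if (any(n < 2)) stop("each group needs n >= 2")
    if (any(s < 0)) stop("sd must be non-negative")
  }
  k <- length(n); N <- sum(n)
  gm <- sum(n * m) / N
  ss_between <- sum(n * (m - gm)^2)
  ss_within <- sum((n - 1) * s^2)
  df1 <- k - 1; df2 <- N - k
  if (ss_within == 0) {
    f <- if (ss_between == 0) 0 else Inf
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
  }
  p <- if (ss_between == 0) 1 else stats::pf(f, df1, df2, lower.tail = FALSE)
  test_result(statistic = f, df = c(df1, df2), p_value = max(p, 1e-300),
              method = "oneway_anova")
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference on k-1 degrees of
#' freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors.
#' @return A [test_result].
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  if (sum(lengths(groups)) < 5) stop("need total n >= 5")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)  # all tied: H = 0 by convention
    return(test_result(statistic = 0, df = length(groups) - 1, p_value = 1,
                       method = "kruskal_wallis"))
  kt <- stats::kruskal.test(x, g)
  test_result(statistic = unname(kt$statistic), df = unname(kt$parameter),
              p_value = kt$p.value, method = "kruskal_wallis")
}

#' Two-sample t test
#'
#' Welch (default) or Student two-sided t test. When both groups have zero
#' variance the test is degenerate: equal means give p = 1 by convention,
#' unequal means are an error.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param variant `"welch"` or `"student"`.
#' @return A [test_result] with `effect` = mean(a) - mean(b) and its 95% CI.
#' @export
two_sample_t <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(test_result(statistic = 0, df = length(a) + length(b) - 2,
                         p_value = 1, method = paste0("t_", variant),
                         effect = 0, ci_low = 0, ci_high = 0))
    stop("both groups have zero variance with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "student"))
  test_result(statistic = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value, method = paste0("t_", variant),
              effect = unname(diff(rev(tt$estimate))),
              ci_low = tt$conf.int[1], ci_high = tt$conf.int[2])
}
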