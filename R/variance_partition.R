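#' Euclidean distance matrix
#'
#' @param x numeric matrix (samples x features), no missing values.
#' @return symmetric distance matrix with zero diagonal.
#' @export
euclidean_distance <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values in input")
  as.matrix(stats::dist(x))
}

# Gower-centred inner-product matrix G from a squared distance matrix
.gower_center <- function(d2) {
  n <- nrow(d2)
  a <- -0.5 * d2
  rm_ <- rowMeans(a); gm <- mean(a)
  a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
}

# SS explained by a factor given G: categorical uses the block identity
# tr(GH) = sum_g u_g' G u_g / n_g (intercept term vanishes on centred G),
# continuous uses the centred single-column projection.
.ss_factor <- function(G, f) {
  if (is.factor(f)) {
    U <- stats::model.matrix(~ f - 1)
    sum(colSums(U * (G %*% U)) / colSums(U))
  } else {
    xc <- f - mean(f)
    drop(crossprod(xc, G %*% xc)) / sum(xc^2)
  }
}

.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

#' Single-factor (marginal) PERMANOVA
#'
#' Permutational multivariate analysis of variance with the factor as the
#' only predictor, so R-squared is the total variance attributable to that
#' factor alone. The squared distance matrix is Gower-centred to G,
#' SS_total = trace(G), SS_factor = trace(HGH) for the factor's hat matrix,
#' pseudo-F = (SS_factor/df1) / (SS_residual/df2), and the p-value comes
#' from permuting sample labels: p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#' With n small enough that n! <= 10080, all relabelings are enumerated and
#' the p-value is exact.
#'
#' @param d distance matrix (or `dist`).
#' @param f factor (categorical, >= 2 levels present) or numeric covariate
#'   (non-zero variance) per sample.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; default auto (n! <= 10080).
#' @return list of class `permanova_result`: `r_squared`, `pseudo_f`,
#'   `p_value`, `df`, `n_permutations`, `exhaustive`.
#' @export
permanova_single_factor <- function(d, f, n_perm = 999, seed = 1L,
                                    exhaustive = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 5) stop("need at least 5 samples")
  if (!isSymmetric(unname(d)) || any(diag(d) != 0))
    stop("d must be a symmetric distance matrix with zero diagonal")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (is.character(f) || is.logical(f)) f <- factor(f)
  if (is.factor(f)) {
    f <- droplevels(f)
    if (nlevels(f) < 2) stop("factor must have >= 2 levels")
    df1 <- nlevels(f) - 1L
  } else {
    if (stats::var(f) == 0) stop("continuous factor has zero variance")
    df1 <- 1L
  }
  stopifnot(length(f) == n)
  df2 <- n - df1 - 1L

  G <- .gower_center(d^2)
  ss_total <- sum(diag(G))
  ss_f <- .ss_factor(G, f)
  r2 <- ss_f / ss_total
  f_obs <- (ss_f / df1) / ((ss_total - ss_f) / df2)

  do_exhaustive <- if (is.null(exhaustive)) factorial(n) <= 10080 else exhaustive
  # degenerate perfect separation gives an infinite F; comparisons stay valid
  eps <- if (is.finite(f_obs)) 1e-12 * max(1, abs(f_obs)) else 0
  if (do_exhaustive) {
    if (factorial(n) > 10080) stop("n too large for exhaustive enumeration")
    P <- .all_perms(n)
    fs <- apply(P, 1, function(p) {
      ssp <- .ss_factor(G, f[p])
      (ssp / df1) / ((ss_total - ssp) / df2)
    })
    p_val <- mean(fs >= f_obs - eps)
    n_used <- nrow(P)
  } else {
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        ssp <- .ss_factor(G, f[sample.int(n)])
        fp <- (ssp / df1) / ((ss_total - ssp) / df2)
        fp >= f_obs - eps
      }, logical(1)))
    })
    p_val <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }

  structure(list(r_squared = r2, pseudo_f = f_obs, p_value = p_val,
                 df = c(df1, df2), n_permutations = n_used,
                 exhaustive = do_exhaustive),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f, pseudo-F = %.3f (df %d, %d), p = %s%s\n",
              x$r_squared, x$pseudo_f, x$df[1], x$df[2],
              format.pval(x$p_value, digits = 3),
              if (x$exhaustive) " [exhaustive]" else ""))
  invisible(x)
}

#' Marginal PERMANOVA variance table
#'
#' Runs [permanova_single_factor()] for each factor independently (each
#' factor is the only predictor in its model), adjusts the p-values with
#' Benjamini-Hochberg across the factor family, and flags significance at
#' adjusted p < `fdr`.
#'
#' @param d distance matrix.
#' @param factors data frame of per-sample factors/covariates.
#' @param n_perm permutations per factor.
#' @param seed base seed (each factor uses `seed + column index`).
#' @param fdr adjusted-p significance threshold (default 0.1).
#' @return data frame: `factor`, `r_squared`, `pseudo_f`, `p_value`,
#'   `p_adjusted`, `significant`, `n_permutations`.
#' @export
variance_table <- function(d, factors, n_perm = 999, seed = 1L, fdr = 0.1) {
  stopifnot(is.data.frame(factors), ncol(factors) >= 1)
  res <- lapply(seq_along(factors), function(i)
    permanova_single_factor(d, factors[[i]], n_perm = n_perm,
                            seed = seed + i))
  out <- data.frame(
    factor = names(factors),
    r_squared = vapply(res, `[[`, numeric(1), "r_squared"),
    pseudo_f = vapply(res, `[[`, numeric(1), "pseudo_f"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    n_permutations = vapply(res, `[[`, numeric(1), "n_permutations"),
    stringsAsFactors = FALSE)
  out$p_adjusted <- adjust_pvalues(out$p_value, "BH")
  out$significant <- out$p_adjusted < fdr
  out
}
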