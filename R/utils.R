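#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic operations in the package route their `seed` argument
# through this helper so that user-level RNG streams are never disturbed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("field '%s': %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (anyNA(x)) stop_field(field, "missing value")
  if (any(x <= 0)) stop_field(field, "must be strictly positive")
  invisible(x)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

#' Construct a test result
#'
#' Light-weight container for a single hypothesis test, used by every
#' statistical routine in the package.
#'
#' @param statistic test statistic (may be `NA` for enumeration tests).
#' @param df degrees of freedom (scalar or vector, e.g. `c(df1, df2)`).
#' @param p_value two-sided p-value in (0, 1].
#' @param method character tag naming the procedure.
#' @param effect,ci_low,ci_high optional effect size and 95% CI.
#' @param p_adjusted optional multiplicity-adjusted p-value.
#'
#' @return An object of class `test_result` (a named list).
#' @export
test_result <- function(statistic = NA_real_, df = NA_real_, p_value,
                        method, effect = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_adjusted = NA_real_) {
  stopifnot(is.numeric(p_value), length(p_value) == 1L)
  if (!is.na(p_value) && (p_value <= 0 || p_value > 1 + 1e-12))
    stop("p_value must lie in (0, 1]")
  structure(
    list(statistic = unname(statistic), df = unname(df),
         p_value = min(unname(p_value), 1), method = method,
         effect = effect, ci_low = ci_low, ci_high = ci_high,
         p_adjusted = p_adjusted),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  if (!all(is.na(x$statistic)))
    cat("  statistic =", format(x$statistic, digits = 5),
        if (!all(is.na(x$df))) paste0("(df = ", paste(format(x$df, digits = 4),
                                                      collapse = ", "), ")"),
        "\n")
  cat("  p =", format.pval(x$p_value, digits = 4), "\n")
  if (!is.na(x$p_adjusted))
    cat("  p_adj =", format.pval(x$p_adjusted, digits = 4), "\n")
  if (!is.na(x$effect))
    cat("  effect =", format(x$effect, digits = 4),
        if (!is.na(x$ci_low)) sprintf("[%.4g, %.4g]", x$ci_low, x$ci_high),
        "\n")
  invisible(x)
}
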