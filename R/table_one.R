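#' Default variable map for the cohort characteristics table
#'
#' Names each clinical variable and the summary/test it receives:
#' categorical variables get N (%) per group and the exact Fisher test;
#' approximately normal continuous variables get mean (SD) and one-way
#' ANOVA, with ALP, bilirubin, ALT and platelets tested on the log10 scale;
#' UDCA treatment years get the Kruskal-Wallis test.
#'
#' @return data frame with columns `variable`, `type`
#'   (`categorical` / `normal` / `normal_log10` / `nonparametric`).
#' @export
table_one_variables <- function() {
  data.frame(
    variable = c("sex", "age", "age_at_diagnosis", "bmi", "ama",
                 "alp_post", "bilirubin", "albumin", "alt", "platelets",
                 "udca_dose", "udca_years", "sequestrants", "antibiotics",
                 "apap", "statins", "ppi", "alcohol", "smoking",
                 "autoimmune_any", "celiac"),
    type = c("categorical", "normal", "normal", "normal", "categorical",
             "normal_log10", "normal_log10", "normal", "normal_log10",
             "normal_log10", "normal", "nonparametric", rep("categorical", 5),
             "categorical", "categorical", "categorical", "categorical"),
    stringsAsFactors = FALSE)
}

#' Published reference cohort characteristics
#'
#' Loads the printed characteristics of the 419-patient UDCA-treated PBC
#' reference cohort that the synthetic generator emulates: per-group counts
#' for the categorical variables and per-group summary statistics (n, mean,
#' SD) for the continuous ones, shipped as plain TSV under `inst/extdata`.
#' These printed tables are inputs: re-running the statistical battery on
#' them reproduces the reference p-values.
#'
#' @return list with data frames `categorical` (`variable`, `level`, `nr`,
#'   `r`, `r_bp`) and `continuous` (`variable`, `group`, `n`, `mean`, `sd`).
#' @export
reference_cohort_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "udcaresponse",
                                  mustWork = TRUE)
  list(categorical = utils::read.delim(path("table1_categorical.tsv"),
                                       stringsAsFactors = FALSE),
       continuous = utils::read.delim(path("table1_continuous.tsv"),
                                      stringsAsFactors = FALSE))
}

#' Build the cohort characteristics table
#'
#' Summarises a classified cohort per response group (N (%) for categorical
#' variables, mean (SD) for continuous ones) and attaches the appropriate
#' group test per variable: exact r x c Fisher for categorical rows, one-way
#' ANOVA for normal continuous rows (log10-transformed where flagged), and
#' Kruskal-Wallis for the non-parametric rows.
#'
#' @param records clinical data frame.
#' @param labels response factor from [classify_response()] (one per row of
#'   `records`).
#' @param variables variable map as from [table_one_variables()]; variables
#'   absent from `records` are skipped.
#'
#' @return data frame with one row per variable level: `variable`, `level`,
#'   one summary column per group, `p_value`, `method`. One-level
#'   categorical variables are emitted with `method = "inapplicable"`.
#' @export
build_table_one <- function(records, labels,
                            variables = table_one_variables()) {
  stopifnot(is.data.frame(records), nrow(records) == length(labels))
  labels <- droplevels(factor(labels))
  grp_names <- levels(labels)
  known <- c("categorical", "normal", "normal_log10", "nonparametric")
  if (!all(variables$type %in% known))
    stop("unknown variable type: ",
         paste(setdiff(variables$type, known), collapse = ", "))

  rows <- list()
  for (k in seq_len(nrow(variables))) {
    var <- variables$variable[k]
    type <- variables$type[k]
    if (is.null(records[[var]])) next
    x <- records[[var]]

    if (type == "categorical") {
      x <- factor(x)
      tab <- table(x, labels)
      if (nrow(tab) < 2 || any(colSums(tab) == 0)) {
        p <- NA_real_; method <- "inapplicable"
      } else {
        ft <- fisher_exact_rxc(unclass(tab))
        p <- ft$p_value; method <- ft$method
      }
      summ <- vapply(grp_names, function(g) {
        n <- tab[, g]
        sprintf("%d (%.1f)", n, 100 * n / sum(n))
      }, character(nrow(tab)))
      if (is.null(dim(summ))) summ <- matrix(summ, nrow = 1,
                                             dimnames = list(NULL, grp_names))
      for (lv in seq_len(nrow(tab)))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = var, level = rownames(tab)[lv],
          as.list(stats::setNames(summ[lv, ], grp_names)),
          p_value = if (lv == 1) p else NA_real_,
          method = if (lv == 1) method else "",
          stringsAsFactors = FALSE, check.names = FALSE)
    } else {
      y <- if (type == "normal_log10") log10(x) else x
      gl <- split(y[!is.na(y)], labels[!is.na(y)])
      res <- if (type == "nonparametric") kruskal_wallis(gl)
             else oneway_anova(gl)
      summ <- vapply(grp_names, function(g) {
        v <- x[labels == g & !is.na(x)]
        sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
      }, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = var, level = "mean_sd",
        as.list(summ), p_value = res$p_value, method = res$method,
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
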