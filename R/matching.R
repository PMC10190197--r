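# documented category -> integer codes used for matching covariates
.match_level_orders <- list(
  sex = c("female", "male"),
  smoking = c("never", "former", "current"),
  alcohol = c("abstinent", "moderate", "excess"))

#' Encode and standardise matching covariates
#'
#' Builds the covariate matrix used for nearest-neighbour confounder
#' matching: categories are converted to integers (documented level orders:
#' smoking never < former < current, alcohol abstinent < moderate < excess,
#' sex female = 0 < male = 1; hospital and any other unlisted factor use
#' alphabetical ordinals), logicals become 0/1, and every column is then
#' mean-centred and scaled to unit variance. Rows with a missing value in
#' any used column are excluded (in particular, records whose BMI would
#' have required imputation are not matched on an imputed value).
#'
#' @param records clinical data frame with a `patient_id` column.
#' @param columns covariates to use (default: sex, age, BMI, sequestrants,
#'   smoking, PPI, antibiotics, hospital).
#' @param level_orders named list of category orders overriding the
#'   defaults.
#' @return standardised numeric matrix with `patient_id` row names;
#'   `attr(, "excluded")` lists ids dropped for missingness.
#' @export
encode_scale_covariates <- function(records,
                                    columns = c("sex", "age", "bmi",
                                                "sequestrants", "smoking",
                                                "ppi", "antibiotics",
                                                "hospital"),
                                    level_orders = list()) {
  stopifnot(is.data.frame(records), !is.null(records$patient_id))
  miss_cols <- setdiff(columns, names(records))
  if (length(miss_cols))
    stop("columns not found: ", paste(miss_cols, collapse = ", "))
  orders <- utils::modifyList(.match_level_orders, level_orders)

  enc <- vapply(columns, function(col) {
    x <- records[[col]]
    if (is.numeric(x)) return(as.numeric(x))
    if (is.logical(x)) return(as.numeric(x))
    x <- as.character(x)
    lv <- if (!is.null(orders[[col]])) orders[[col]]
          else sort(unique(x[!is.na(x)]))
    bad <- !is.na(x) & !x %in% lv
    if (any(bad))
      stop("unknown level '", x[bad][1], "' in column '", col, "'")
    as.numeric(match(x, lv) - 1)
  }, numeric(nrow(records)))

  keep <- stats::complete.cases(enc)
  excluded <- records$patient_id[!keep]
  enc <- enc[keep, , drop = FALSE]
  sds <- apply(enc, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance covariate(s): ",
         paste(columns[sds == 0], collapse = ", "))
  enc <- scale(enc)
  rownames(enc) <- records$patient_id[keep]
  attr(enc, "excluded") <- excluded
  enc
}

#' Nearest-neighbour matching of cases to control pools
#'
#' For every case and every candidate pool, selects the pool member at
#' minimum Euclidean distance (with replacement across cases -- matching is
#' not iteratively rebalanced, so two cases may share a control). Ties are
#' broken deterministically by the candidate's position in the pool's row
#' order (lowest identifier ordinal). The per-pool matched sets are the
#' deduplicated selected controls, so a matched set can be smaller than the
#' case count.
#'
#' @param cases numeric matrix of standardised case covariates (row names =
#'   ids).
#' @param pools named list of candidate matrices on the same columns.
#' @return object of class `match_result`: `assignments` data frame
#'   (`case_id`, `pool`, `match_id`, `distance`) and `matched`, the
#'   deduplicated id sets per pool.
#' @export
nearest_match <- function(cases, pools) {
  stopifnot(is.matrix(cases), is.list(pools), length(pools) >= 1)
  if (any(vapply(pools, nrow, integer(1)) == 0)) stop("empty candidate pool")
  rows <- list()
  for (pn in names(pools)) {
    pool <- pools[[pn]]
    stopifnot(ncol(pool) == ncol(cases))
    for (i in seq_len(nrow(cases))) {
      dd <- sqrt(colSums((t(pool) - cases[i, ])^2))
      best <- which(dd <= min(dd) + 1e-12)[1]   # tie: lowest ordinal
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = rownames(cases)[i], pool = pn,
        match_id = rownames(pool)[best], distance = dd[best],
        stringsAsFactors = FALSE)
    }
  }
  assignments <- do.call(rbind, rows)
  matched <- lapply(split(assignments$match_id, assignments$pool), unique)
  structure(list(assignments = assignments, matched = matched),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("nearest-neighbour matching:",
      length(unique(x$assignments$case_id)), "cases\n")
  for (pn in names(x$matched))
    cat(sprintf("  pool %s: %d unique matches\n", pn, length(x$matched[[pn]])))
  invisible(x)
}

#' Match the bad-prognosis responder subgroup on confounders
#'
#' Convenience driver for the R_BP matching procedure: encodes and
#' standardises the matching covariates on the full cohort (so all groups
#' share one scale), then finds, for each R_BP case, the nearest NR and the
#' nearest R sample.
#'
#' @param records clinical data frame.
#' @param labels response factor aligned with `records`.
#' @param columns matching covariates (see [encode_scale_covariates()]).
#' @return A `match_result`; `attr(, "case_ids")` holds the R_BP ids used.
#' @export
match_rbp_subset <- function(records, labels,
                             columns = c("sex", "age", "bmi", "sequestrants",
                                         "smoking", "ppi", "antibiotics",
                                         "hospital")) {
  labels <- factor(labels)
  enc <- encode_scale_covariates(records, columns)
  lab <- labels[match(rownames(enc), records$patient_id)]
  if (!any(lab == "R_BP")) stop("no R_BP cases to match")
  res <- nearest_match(enc[lab == "R_BP", , drop = FALSE],
                       list(NR = enc[lab == "NR", , drop = FALSE],
                            R = enc[lab == "R", , drop = FALSE]))
  attr(res, "case_ids") <- rownames(enc)[lab == "R_BP"]
  res
}
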