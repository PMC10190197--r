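#' Read an LC-MS feature table from TSV
#'
#' Expects a header row; metadata columns are named by `schema` and every
#' remaining column is a feature. Validates sample-id uniqueness and
#' non-negativity and reports offending rows/columns.
#'
#' @param path TSV file.
#' @param schema named list mapping the metadata roles `sample_id`,
#'   `run_order`, `role` (and optionally `fecal_mass`) to column names.
#' @param matrix_type passed to [feature_run()].
#' @return A [feature_run].
#' @export
read_feature_table <- function(path,
                               schema = list(sample_id = "sample_id",
                                             run_order = "run_order",
                                             role = "role",
                                             fecal_mass = "fecal_mass"),
                               matrix_type = "fecal") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df) || !ncol(df)) stop("empty feature table: ", path)
  needed <- unlist(schema[c("sample_id", "run_order", "role")])
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("schema columns missing: ", paste(missing, collapse = ", "))
  meta_cols <- intersect(unlist(schema), names(df))
  feat_cols <- setdiff(names(df), meta_cols)
  if (!length(feat_cols)) stop("no feature columns found")

  ids <- as.character(df[[schema$sample_id]])
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  intens <- as.matrix(df[feat_cols])
  if (!is.numeric(intens)) stop("non-numeric feature column(s)")
  neg <- which(intens < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative intensity at row ", neg[1, 1], ", feature '",
         feat_cols[neg[1, 2]], "'")
  rownames(intens) <- ids

  samples <- data.frame(sample_id = ids,
                        run_order = df[[schema$run_order]],
                        role = df[[schema$role]],
                        stringsAsFactors = FALSE)
  fm <- schema$fecal_mass
  samples$fecal_mass <- if (!is.null(fm) && fm %in% names(df)) df[[fm]] else NA_real_
  feature_run(samples = samples, intensities = intens,
              matrix_type = matrix_type)
}

#' Write an LC-MS feature table to TSV
#'
#' @param run a [feature_run].
#' @param path output file.
#' @export
write_feature_table <- function(run, path) {
  stopifnot(inherits(run, "feature_run"))
  df <- cbind(run$samples, as.data.frame(run$intensities, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxon count table from TSV
#'
#' First column is the sample identifier; every other column a taxon's
#' integer counts.
#'
#' @param path TSV file.
#' @return A [count_table].
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df) || ncol(df) < 2) stop("empty count table: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[-1])
  rownames(m) <- ids
  count_table(m)
}

#' Write a taxon count table to TSV
#' @param tbl a [count_table].
#' @param path output file.
#' @export
write_count_table <- function(tbl, path) {
  df <- data.frame(sample_id = rownames(tbl),
                   as.data.frame(unclass(tbl), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny in newick format
#'
#' Standard newick dialect with branch lengths required.
#'
#' @param path newick file.
#' @return An `ape::phylo`.
#' @export
read_newick_tree <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree)) stop("unparseable newick file: ", path)
  if (is.null(tree$edge.length)) stop("newick tree lacks branch lengths")
  tree
}

#' Write a synthetic cohort bundle to plain-text files
#'
#' Writes clinical TSV, feature-intensity TSV, taxon-count TSV, newick tree
#' and a ground-truth JSON into a directory.
#'
#' @param bundle a `cohort_bundle` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_feature_table(bundle$ms_run, file.path(dir, "ms_intensities.tsv"))
  write_count_table(bundle$counts, file.path(dir, "taxon_counts.tsv"))
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(labels = as.character(bundle$truth$labels),
         effect_sizes_ms = bundle$truth$effect_sizes_ms,
         effect_sizes_taxa = bundle$truth$effect_sizes_taxa),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on a cohort bundle
#'
#' Executes, in order: response classification, cohort characteristics
#' table, LC-MS preprocessing, compositional microbiome processing,
#' marginal PERMANOVA variance partitioning on each omics matrix,
#' per-feature mixed-model association testing, R_BP confounder matching,
#' matched-subset differential abundance, and the taxa-metabolite
#' correlation screen. Per-stage TSVs and a JSON run manifest (seeds,
#' parameters, package version) are written when `outdir` is given; the
#' manifest contains everything needed to reproduce the run byte-for-byte.
#'
#' @param bundle a `cohort_bundle` (from [generate_cohort()] or assembled
#'   from files).
#' @param outdir optional output directory.
#' @param n_perm PERMANOVA permutations.
#' @param seed seed governing all stochastic stages.
#' @param fdr BH threshold used throughout (default 0.1).
#' @param prevalence_threshold taxon prevalence filter (default 0.10).
#' @return list of per-stage results, invisibly when writing.
#' @export
run_pipeline <- function(bundle, outdir = NULL, n_perm = 999, seed = 1L,
                         fdr = 0.1, prevalence_threshold = 0.10) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  out <- list()

  out$labels <- .stage("classify", classify_response(bundle$clinical))
  out$table_one <- .stage("table-one",
                          build_table_one(bundle$clinical, out$labels))
  out$ms <- .stage("preprocess-ms", preprocess_ms(bundle$ms_run, seed = seed))
  out$microbiome <- .stage("microbiome",
                           process_microbiome(bundle$counts, bundle$tree,
                                              threshold = prevalence_threshold))

  study <- bundle$ms_run$samples$sample_id[bundle$ms_run$samples$role == "study"]
  ms_mat <- out$ms$run$intensities[study, , drop = FALSE]
  idx <- match(study, bundle$clinical$patient_id)
  fac <- data.frame(response = out$labels[idx],
                    sex = bundle$clinical$sex[idx],
                    age = bundle$clinical$age[idx],
                    bmi = bundle$clinical$bmi[idx],
                    antibiotics = bundle$clinical$antibiotics[idx],
                    ppi = bundle$clinical$ppi[idx],
                    smoking = bundle$clinical$smoking[idx],
                    sequestrants = bundle$clinical$sequestrants[idx],
                    hospital = bundle$clinical$hospital[idx])
  out$permanova_ms <- .stage("permanova",
    variance_table(euclidean_distance(ms_mat), fac, n_perm = n_perm,
                   seed = seed, fdr = fdr))
  cidx <- match(rownames(out$microbiome$clr), bundle$clinical$patient_id)
  out$permanova_taxa <- .stage("permanova",
    variance_table(euclidean_distance(out$microbiome$clr), fac[cidx, ],
                   n_perm = n_perm, seed = seed, fdr = fdr))

  covs <- fac[c("sex", "age", "bmi", "antibiotics", "ppi", "smoking")]
  out$association_ms <- .stage("associate",
    test_features_lmm(ms_mat, fac$response, covs, fac$hospital, fdr = fdr))

  out$match <- .stage("match", match_rbp_subset(bundle$clinical, out$labels))
  matched_ids <- unique(c(attr(out$match, "case_ids"),
                          unlist(out$match$matched)))
  filt <- out$microbiome$filtered
  sub_ids <- intersect(matched_ids, rownames(filt))
  sub_counts <- filt[sub_ids, , drop = FALSE]
  sub_counts <- sub_counts[, colSums(sub_counts) > 0, drop = FALSE]
  class(sub_counts) <- class(filt)
  midx <- match(sub_ids, bundle$clinical$patient_id)
  out$matched_da <- .stage("matched-da",
    da_clr_lm(sub_counts,
              data.frame(response = out$labels[midx],
                         age = bundle$clinical$age[midx],
                         bmi = bundle$clinical$bmi[midx]),
              p_threshold = fdr))

  sig_taxa <- out$matched_da$taxon[out$matched_da$significant]
  sig_feat <- out$association_ms$feature[out$association_ms$significant]
  if (length(sig_taxa) && length(sig_feat)) {
    common <- intersect(rownames(out$microbiome$clr), study)
    out$correlations <- .stage("correlate",
      correlation_screen(
        out$microbiome$clr[common, sig_taxa, drop = FALSE],
        out$ms$run$intensities[common, sig_feat, drop = FALSE],
        fdr = fdr))
  } else {
    out$correlations <- NULL
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(data.frame(patient_id = bundle$clinical$patient_id,
                  label = as.character(out$labels)), "response_labels.tsv")
    wt(out$table_one, "table_one.tsv")
    wt(out$ms$stats, "ms_feature_filters.tsv")
    wt(out$microbiome$alpha, "alpha_diversity.tsv")
    wt(out$permanova_ms, "permanova_ms.tsv")
    wt(out$permanova_taxa, "permanova_taxa.tsv")
    wt(out$association_ms, "association_ms.tsv")
    wt(out$match$assignments, "matched_samples.tsv")
    wt(out$matched_da, "matched_da.tsv")
    if (!is.null(out$correlations)) wt(out$correlations, "correlations.tsv")
    manifest <- list(
      package = "udcaresponse",
      version = as.character(utils::packageVersion("udcaresponse")),
      seed = seed, n_perm = n_perm, fdr = fdr,
      prevalence_threshold = prevalence_threshold,
      config = bundle$config[setdiff(names(bundle$config),
                                     c("effect_sizes_ms", "effect_sizes_taxa",
                                       "structural_zeros"))])
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
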