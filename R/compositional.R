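#' Construct a taxon count table
#'
#' @param counts non-negative integer matrix, samples in rows, taxa in
#'   columns; every sample must have at least one positive count.
#' @return object of class `count_table` (the validated matrix).
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!is_wholenumber(counts) || any(counts < 0))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(utils::head(rownames(counts)[rowSums(counts) == 0]), collapse = ", "))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("ASV%05d", seq_len(ncol(counts)))
  structure(counts, class = c("count_table", "matrix", "array"))
}

#' Prevalence filter
#'
#' Keeps taxa with a nonzero count in at least `threshold` of samples
#' (default 10%, i.e. discard features with a zero count in more than 90%
#' of samples).
#'
#' @param tbl a [count_table].
#' @param threshold prevalence threshold in (0, 1).
#' @return The filtered [count_table]; `attr(, "prevalence")` holds the
#'   per-taxon prevalence of the input.
#' @export
prevalence_filter <- function(tbl, threshold = 0.10) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  prev <- colMeans(tbl > 0)
  keep <- prev >= threshold
  if (!any(keep)) stop("no taxa pass the prevalence filter")
  out <- tbl[, keep, drop = FALSE]
  class(out) <- class(tbl)
  attr(out, "prevalence") <- prev
  out
}

#' Bayesian-multiplicative replacement of count zeros
#'
#' Replaces zero counts by prior-based pseudo-proportions and adjusts the
#' observed parts multiplicatively so each sample still sums to one,
#' preserving the ratios between observed parts exactly. For a sample with
#' total n, a zero cell of part j receives t_j * s / (n + s), where t is the
#' prior proportion vector and s the prior strength; samples without zeros
#' reduce exactly to the simple closure x / sum(x).
#'
#' The default prior follows the geometric Bayesian-multiplicative (GBM)
#' convention: t is estimated from the data as the (renormalised) geometric
#' mean of each part's positive proportions across samples, with
#' square-root-of-total prior strength s = sqrt(n). Both are overridable.
#'
#' @param tbl a prevalence-filtered [count_table] (no all-zero sample, every
#'   part positive somewhere).
#' @param strength `"sqrt"` (s = sqrt(n), default), `"bayes_laplace"`
#'   (s = number of parts) or `"perks"` (s = 1).
#' @param prior_probs optional explicit prior proportion vector `t`
#'   (positive, summing to 1); default geometric-mean estimate.
#' @return matrix of strictly positive proportions (rows sum to 1).
#' @export
gbm_zero_replace <- function(tbl,
                             strength = c("sqrt", "bayes_laplace", "perks"),
                             prior_probs = NULL) {
  strength <- match.arg(strength)
  x <- unclass(as.matrix(tbl))
  if (any(rowSums(x) == 0)) stop("all-zero sample")
  n <- rowSums(x)
  D <- ncol(x)
  p <- x / n

  if (is.null(prior_probs)) {
    t_j <- apply(p, 2, function(col) {
      pos <- col[col > 0]
      if (!length(pos))
        stop("part with no positive count; apply a prevalence filter first")
      exp(mean(log(pos)))
    })
    t_j <- t_j / sum(t_j)
  } else {
    if (length(prior_probs) != D || any(prior_probs <= 0))
      stop("prior_probs must be positive with one entry per part")
    t_j <- prior_probs / sum(prior_probs)
  }
  s <- switch(strength, sqrt = sqrt(n), bayes_laplace = rep(D, nrow(x)),
              perks = rep(1, nrow(x)))

  out <- p
  for (i in which(rowSums(x == 0) > 0)) {
    z <- x[i, ] == 0
    repl <- t_j[z] * s[i] / (n[i] + s[i])
    tot_repl <- sum(repl)
    if (tot_repl >= 1) stop("replacement mass >= 1; prior too strong")
    out[i, z] <- repl
    out[i, !z] <- p[i, !z] * (1 - tot_repl)
  }
  out
}

#' Centred log-ratio transform
#'
#' Maps each strictly positive composition row x to log(x) - mean(log(x)).
#'
#' @param props matrix of strictly positive values (rows are compositions).
#' @return numeric matrix of clr coordinates (rows sum to 0).
#' @export
clr_transform <- function(props) {
  props <- as.matrix(props)
  if (any(!is.finite(props)) || any(props <= 0))
    stop("clr requires strictly positive entries")
  lx <- log(props)
  sweep(lx, 1, rowMeans(lx), "-")
}

#' Alpha diversity per sample
#'
#' Richness (observed taxa), Shannon entropy H = -sum p log p (nats),
#' Simpson concentration D = sum p^2, Pielou evenness H / log(richness)
#' and Simpson evenness (1/D) / richness. Computed on raw (unfiltered)
#' counts.
#'
#' @param tbl a [count_table].
#' @return data frame with one row per sample.
#' @export
alpha_diversity <- function(tbl) {
  x <- unclass(as.matrix(tbl))
  if (any(rowSums(x) == 0)) stop("empty sample")
  out <- t(apply(x, 1, function(v) {
    p <- v[v > 0] / sum(v)
    S <- length(p)
    H <- -sum(p * log(p))
    D <- sum(p^2)
    c(richness = S, shannon = H, simpson = D,
      pielou_evenness = if (S > 1) H / log(S) else NA_real_,
      simpson_evenness = (1 / D) / S)
  }))
  data.frame(sample_id = rownames(x), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Faith's phylogenetic diversity
#'
#' For each sample, the total branch length of the minimal subtree spanning
#' the observed taxa and the tree root. Implemented as the sum of branch
#' lengths over edges whose subtended tips intersect the observed set,
#' using a sparse edge-by-tip incidence matrix so hundreds of samples over
#' thousands of taxa stay cheap. A positive root edge (`tree$root.edge`),
#' if present, is included for every non-empty sample.
#'
#' @param tbl a [count_table]; all its taxa must be tips of `tree`.
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @return named numeric vector of PD values per sample.
#' @export
faith_pd <- function(tbl, tree) {
  x <- unclass(as.matrix(tbl))
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  missing <- setdiff(colnames(x), tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))

  ntip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  edge_of <- integer(max(tree$edge))        # edge leading into each node
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]

  # sparse incidence: M[e, t] = 1 iff edge e lies on the root path of tip t
  paths <- vector("list", ntip)
  for (tip in seq_len(ntip)) {
    node <- tip
    es <- integer(0)
    while (node != root) {
      es[length(es) + 1L] <- edge_of[node]
      node <- parent[node]
    }
    paths[[tip]] <- es
  }
  M <- Matrix::sparseMatrix(i = unlist(paths),
                            j = rep(seq_len(ntip), lengths(paths)),
                            x = 1, dims = c(nrow(tree$edge), ntip))

  pres <- matrix(0, ntip, nrow(x))
  hit <- match(colnames(x), tree$tip.label)
  pres[hit, ] <- t(x > 0) * 1
  pres <- Matrix::Matrix(pres, sparse = TRUE)
  on_path <- (M %*% pres) > 0
  pd <- as.numeric(tree$edge.length %*% on_path)
  if (!is.null(tree$root.edge) && tree$root.edge > 0)
    pd <- pd + tree$root.edge
  stats::setNames(pd, rownames(x))
}

#' Principal component scores
#'
#' Column-centres the input and computes principal components by singular
#' value decomposition. On clr-transformed taxon abundances this is the
#' standard Euclidean (Aitchison) view of beta-diversity.
#'
#' @param x numeric matrix (samples x features).
#' @param n_components number of components (must not exceed the rank).
#' @return list with `scores` (samples x components), `explained_variance`
#'   (proportions) and `loadings`.
#' @export
pca_scores <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values")
  xc <- sweep(x, 2, colMeans(x), "-")
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (n_components > rank)
    stop("n_components exceeds the matrix rank (", rank, ")")
  idx <- seq_len(n_components)
  scores <- sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], n_components)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", idx)
  list(scores = scores,
       explained_variance = (sv$d^2 / sum(sv$d^2))[idx],
       loadings = sv$v[, idx, drop = FALSE])
}

#' Standard compositional processing of a count table
#'
#' Prevalence filter, Bayesian-multiplicative zero replacement and clr
#' transform, in that order; alpha diversity is computed on the raw
#' (unfiltered) counts.
#'
#' @param tbl a [count_table].
#' @param tree optional phylogeny for Faith's PD.
#' @param threshold prevalence threshold.
#' @return list with `clr` matrix, `filtered` counts, `alpha` data frame
#'   (including `faith_pd` when a tree is supplied) and `pca` scores.
#' @export
process_microbiome <- function(tbl, tree = NULL, threshold = 0.10) {
  filtered <- prevalence_filter(tbl, threshold)
  clr <- clr_transform(gbm_zero_replace(filtered))
  alpha <- alpha_diversity(tbl)
  if (!is.null(tree)) alpha$faith_pd <- unname(faith_pd(tbl, tree))
  list(clr = clr, filtered = filtered, alpha = alpha,
       pca = pca_scores(clr, n_components = min(5, nrow(clr) - 1, ncol(clr))))
}
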