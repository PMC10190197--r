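#' Construct an LC-MS feature run
#'
#' Container for a sample x feature intensity matrix with run metadata:
#' unique run order per injection, a study/QC role per sample, optional
#' fecal mass (mg) for fecal matrices, a per-feature limit of detection and
#' optional bile-acid annotations.
#'
#' @param samples data frame with columns `sample_id`, `run_order`, `role`
#'   (`"study"` or `"QC"`), optionally `fecal_mass`.
#' @param intensities numeric matrix (samples x features), non-negative
#'   where present; `NA` marks below-LOD censored entries.
#' @param lod optional per-feature detection limit.
#' @param features optional annotation data frame (first column feature id).
#' @param matrix_type `"fecal"`, `"serum"` or `"urine"`.
#' @return object of class `feature_run`.
#' @export
feature_run <- function(samples, intensities, lod = NULL, features = NULL,
                        matrix_type = c("fecal", "serum", "urine")) {
  matrix_type <- match.arg(matrix_type)
  stopifnot(is.data.frame(samples), is.matrix(intensities),
            nrow(samples) == nrow(intensities))
  for (f in c("sample_id", "run_order", "role"))
    if (is.null(samples[[f]])) stop_field(f, "missing from samples")
  if (anyDuplicated(samples$run_order)) stop("run_order must be unique")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (!all(samples$role %in% c("study", "QC")))
    stop("role must be 'study' or 'QC'")
  if (any(intensities < 0, na.rm = TRUE)) stop("negative intensities")
  if (!is.null(lod) && length(lod) != ncol(intensities))
    stop("lod must have one entry per feature")
  structure(list(samples = samples, intensities = intensities, lod = lod,
                 features = features, matrix_type = matrix_type,
                 log_scale = FALSE),
            class = "feature_run")
}

#' @export
print.feature_run <- function(x, ...) {
  cat(sprintf("feature_run: %d samples (%d QC) x %d features [%s%s]\n",
              nrow(x$intensities), sum(x$samples$role == "QC"),
              ncol(x$intensities), x$matrix_type,
              if (x$log_scale) ", log scale" else ""))
  invisible(x)
}

.qc_idx <- function(run) which(run$samples$role == "QC")

# default operational LOD: half the minimum positive QC intensity per feature
.default_lod <- function(run) {
  qc <- run$intensities[.qc_idx(run), , drop = FALSE]
  apply(qc, 2, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) return(0)
    min(v) * 0.5
  })
}

#' QC-anchored loess drift correction
#'
#' Corrects for signal intensity decay along the acquisition run: the QC
#' injections' total ion intensity (TIC) is smoothed against run order with
#' locally weighted regression, the smooth is evaluated at every sample's
#' run order (linear extrapolation beyond the QC range), normalised to mean
#' one, and every feature intensity is divided by it. Normalising the smooth
#' to mean one makes the correction scale-equivariant: a global rescaling of
#' all intensities passes through unchanged.
#'
#' @param run a [feature_run] with >= 2 QC samples.
#' @param span loess span in (0, 1].
#' @param degree local polynomial degree (2 by default; fits with too few
#'   QC points for the requested span fall back to a global polynomial).
#' @return The corrected [feature_run].
#' @export
drift_correct_loess <- function(run, span = 0.75, degree = 2) {
  stopifnot(inherits(run, "feature_run"))
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  qi <- .qc_idx(run)
  if (length(qi) < 2) stop("need at least 2 QC samples")
  tic <- rowSums(run$intensities[qi, , drop = FALSE], na.rm = TRUE)
  if (all(tic == 0)) stop("all QC total ion intensities are zero")
  x_qc <- run$samples$run_order[qi]
  x_all <- run$samples$run_order

  fit <- tryCatch(
    stats::loess(tic ~ x_qc, span = span, degree = degree,
                 control = stats::loess.control(surface = "direct")),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- stats::lm(tic ~ stats::poly(x_qc, min(degree, length(qi) - 1),
                                       raw = TRUE))

  lo <- min(x_qc); hi <- max(x_qc)
  x_clamp <- pmin(pmax(x_all, lo), hi)
  sm <- as.numeric(stats::predict(fit, newdata = data.frame(x_qc = x_clamp)))
  # linear extrapolation beyond the QC range from the boundary slope
  eps <- max((hi - lo) * 1e-3, 1e-9)
  slope_lo <- diff(stats::predict(fit, data.frame(x_qc = c(lo, lo + eps)))) / eps
  slope_hi <- diff(stats::predict(fit, data.frame(x_qc = c(hi - eps, hi)))) / eps
  below <- x_all < lo; above <- x_all > hi
  sm[below] <- sm[below] + slope_lo * (x_all[below] - lo)
  sm[above] <- sm[above] + slope_hi * (x_all[above] - hi)

  w <- sm / mean(sm)
  if (any(w <= 0)) stop("drift smooth crosses zero; check QC coverage")
  out <- run
  out$intensities <- run$intensities / w
  if (!is.null(run$lod)) out$lod <- run$lod  # LOD stays on the raw scale
  attr(out, "drift_smooth") <- w
  out
}

#' Two-stage QC feature filtering
#'
#' Stage 1 discards features below the limit of detection in more than
#' `qc_lod_max` of QC samples. Stage 2 discards surviving features whose QC
#' coefficient of variation exceeds `qc_cv_max` or that are below LOD in
#' more than `study_lod_max` of study samples. Missing (censored) entries
#' count as below LOD. Per-feature statistics are returned for every
#' feature, kept or not.
#'
#' @param run a drift-corrected [feature_run].
#' @param qc_lod_max,qc_cv_max,study_lod_max filter thresholds (defaults
#'   0.9, 0.3, 0.2).
#' @return list with the filtered `run` and a `stats` data frame
#'   (`feature_id`, `qc_cv`, `frac_below_lod_qc`, `frac_below_lod_study`,
#'   `keep`, `reason`).
#' @export
apply_feature_filters <- function(run, qc_lod_max = 0.9, qc_cv_max = 0.3,
                                  study_lod_max = 0.2) {
  stopifnot(inherits(run, "feature_run"))
  qi <- .qc_idx(run); si <- which(run$samples$role == "study")
  if (!length(qi)) stop("no QC samples")
  lod <- if (is.null(run$lod)) .default_lod(run) else run$lod

  below <- function(rows) {
    m <- run$intensities[rows, , drop = FALSE]
    colMeans(is.na(m) | sweep(m, 2, lod, "<"), na.rm = FALSE)
  }
  frac_qc <- below(qi)
  frac_study <- below(si)
  qc_cv <- apply(run$intensities[qi, , drop = FALSE], 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    stats::sd(v) / mean(v)
  })

  reason <- rep("", ncol(run$intensities))
  reason[frac_qc > qc_lod_max] <- "qc_lod"                     # stage 1
  s2 <- reason == ""
  reason[s2 & (is.na(qc_cv) | qc_cv > qc_cv_max)] <- "qc_cv"   # stage 2
  s2 <- reason == ""
  reason[s2 & frac_study > study_lod_max] <- "study_lod"
  keep <- reason == ""

  stats_df <- data.frame(
    feature_id = colnames(run$intensities), qc_cv = qc_cv,
    frac_below_lod_qc = frac_qc, frac_below_lod_study = frac_study,
    keep = keep, reason = reason, row.names = NULL,
    stringsAsFactors = FALSE)

  out <- run
  out$intensities <- run$intensities[, keep, drop = FALSE]
  out$lod <- lod[keep]
  if (!is.null(run$features))
    out$features <- run$features[keep, , drop = FALSE]
  list(run = out, stats = stats_df)
}

#' Normalise fecal intensities by fecal mass
#'
#' Divides each fecal sample's intensities by the milligrams of fecal
#' material used for extraction. Non-fecal matrices pass through untouched.
#' QC samples (pooled aliquots without a mass) also pass through.
#'
#' @param run a [feature_run].
#' @return The normalised [feature_run].
#' @export
normalize_fecal_mass <- function(run) {
  stopifnot(inherits(run, "feature_run"))
  if (run$matrix_type != "fecal") return(run)
  si <- which(run$samples$role == "study")
  mass <- run$samples$fecal_mass[si]
  if (anyNA(mass) || any(mass <= 0))
    stop_field("fecal_mass", "missing or non-positive on a fecal study sample")
  out <- run
  out$intensities[si, ] <- run$intensities[si, , drop = FALSE] / mass
  out
}

#' Log transform, left-censored imputation and mean-centring
#'
#' Natural-log transforms the intensities, imputes missing (below-LOD,
#' missing-not-at-random) entries in the QRILC style, then mean-centres each
#' feature. The imputation fits, per feature, a normal distribution to the
#' observed log values by regressing their order statistics on the normal
#' quantiles of the upper (1 - censored fraction) tail -- a quantile-based
#' fit robust to the censoring -- and draws imputed values from the fitted
#' lower tail truncated strictly below the feature's observed minimum.
#'
#' @param run a filtered [feature_run].
#' @param seed RNG seed for the imputation draws.
#' @return The transformed [feature_run] (`log_scale = TRUE`), with
#'   attribute `imputed` marking imputed cells.
#' @export
log_impute_center <- function(run, seed = 1L) {
  stopifnot(inherits(run, "feature_run"))
  if (run$log_scale) stop("run is already on the log scale")
  x <- run$intensities
  if (any(x <= 0, na.rm = TRUE)) stop("non-positive intensity; cannot log")
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 3))
    stop("feature(s) with fewer than 3 observed values: ",
         paste(colnames(x)[n_obs < 3], collapse = ", "))
  lx <- log(x)
  imputed <- is.na(lx)

  with_seed(seed, {
    for (j in which(colSums(imputed) > 0)) {
      obs <- sort(lx[!imputed[, j], j])
      cf <- mean(imputed[, j])                # censored fraction
      pr <- cf + (1 - cf) * stats::ppoints(length(obs))
      fit <- stats::lm.fit(cbind(1, stats::qnorm(pr)), obs)
      mu <- fit$coefficients[1]
      sd_ <- max(fit$coefficients[2], 1e-8)
      p_max <- max(stats::pnorm(min(obs), mu, sd_), 1e-10)
      u <- stats::runif(sum(imputed[, j])) * p_max * (1 - 1e-12)
      lx[imputed[, j], j] <- stats::qnorm(u, mu, sd_)
    }
  })

  lx <- sweep(lx, 2, colMeans(lx), "-")
  out <- run
  out$intensities <- lx
  out$log_scale <- TRUE
  attr(out, "imputed") <- imputed
  out
}

#' Probabilistic quotient normalisation
#'
#' Corrects sample-to-sample dilution: each spectrum is divided by the
#' median, over features, of its quotients to a reference spectrum (the
#' feature-wise median spectrum of all samples, or of the QC samples).
#'
#' @param spectra positive numeric matrix (samples x features), >= 2 samples.
#' @param reference `"median"` (default) or `"qc"`.
#' @param roles sample roles (needed when `reference = "qc"`).
#' @return list with `normalized` spectra and the estimated `dilution`
#'   factor per sample.
#' @export
pqn_normalize <- function(spectra, reference = c("median", "qc"),
                          roles = NULL) {
  reference <- match.arg(reference)
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2) stop("need at least 2 samples")
  ref_rows <- if (reference == "qc") {
    if (is.null(roles)) stop("roles required for reference = 'qc'")
    which(roles == "QC")
  } else seq_len(nrow(spectra))
  ref <- apply(spectra[ref_rows, , drop = FALSE], 2, stats::median)
  if (any(!is.finite(ref)) || any(ref <= 0))
    stop("reference spectrum has non-positive entries")
  dil <- apply(sweep(spectra, 2, ref, "/"), 1, stats::median)
  list(normalized = spectra / dil, dilution = dil)
}

#' Area under a spectral peak
#'
#' Trapezoidal integral of intensity over a ppm window, with linear
#' interpolation at the window edges.
#'
#' @param ppm numeric vector of chemical shifts (any order).
#' @param intensity intensities at `ppm`.
#' @param window length-2 ppm interval.
#' @return The integrated area (numeric scalar).
#' @export
peak_auc <- function(ppm, intensity, window) {
  stopifnot(length(ppm) == length(intensity), length(window) == 2)
  o <- order(ppm)
  ppm <- ppm[o]; intensity <- intensity[o]
  window <- sort(window)
  if (window[1] < min(ppm) || window[2] > max(ppm))
    stop("window outside spectral range")
  inside <- ppm > window[1] & ppm < window[2]
  x <- c(window[1], ppm[inside], window[2])
  y <- c(stats::approx(ppm, intensity, xout = window)$y[1],
         intensity[inside],
         stats::approx(ppm, intensity, xout = window)$y[2])
  if (length(unique(x)) < 2) stop("empty integration window")
  pracma::trapz(x, y)
}

#' Bile-acid family sums
#'
#' Appends derived features holding per-sample summed intensities for each
#' bile-acid family (on the pre-log intensity scale). With the default map
#' built from the run's annotations this yields glycine- and
#' taurine-conjugated totals, per-compound conjugated + unconjugated totals,
#' and the total bile-acid sum.
#'
#' @param run a [feature_run] on the intensity (not log) scale.
#' @param family_map data frame (`feature_id`, `family`), possibly mapping a
#'   feature into several families; defaults to [ba_family_map()] on the
#'   run's annotations.
#' @return The [feature_run] with family columns appended.
#' @export
compute_ba_families <- function(run, family_map = ba_family_map(run$features)) {
  stopifnot(inherits(run, "feature_run"))
  if (run$log_scale) stop("family sums must be computed on the intensity scale")
  fams <- unique(family_map$family)
  if (!length(fams)) stop("empty family map")
  sums <- vapply(fams, function(f) {
    members <- family_map$feature_id[family_map$family == f]
    idx <- match(members, colnames(run$intensities))
    if (!length(idx) || anyNA(idx))
      stop("family '", f, "' has no (or unknown) member features")
    # censored members contribute ~0 to the sum; an all-censored family
    # value stays censored (NA) and is imputed downstream
    s <- rowSums(run$intensities[, idx, drop = FALSE], na.rm = TRUE)
    s[rowSums(!is.na(run$intensities[, idx, drop = FALSE])) == 0] <- NA_real_
    s
  }, numeric(nrow(run$intensities)))
  out <- run
  out$intensities <- cbind(run$intensities, sums)
  if (!is.null(run$lod)) out$lod <- c(run$lod, rep(0, length(fams)))
  if (!is.null(run$features)) {
    der <- run$features[rep(NA_integer_, length(fams)), , drop = FALSE]
    der[[1]] <- fams
    out$features <- rbind(cbind(run$features, derived = FALSE),
                          cbind(der, derived = TRUE))
  }
  out
}

#' Default bile-acid family map from feature annotations
#'
#' @param features annotation data frame with `feature_id`, `ba`,
#'   `conjugation`.
#' @return data frame (`feature_id`, `family`) in long form.
#' @export
ba_family_map <- function(features) {
  stopifnot(all(c("feature_id", "ba", "conjugation") %in% names(features)))
  rbind(
    data.frame(feature_id = features$feature_id[features$conjugation == "glyco"],
               family = "G-BAs"),
    data.frame(feature_id = features$feature_id[features$conjugation == "tauro"],
               family = "T-BAs"),
    data.frame(feature_id = features$feature_id,
               family = paste0(features$ba, "_total")),
    data.frame(feature_id = features$feature_id, family = "total_BA"))
}

#' Run the full LC-MS preprocessing chain
#'
#' Fixed stage order: drift correction, two-stage QC filtering, fecal-mass
#' normalisation, bile-acid family sums, then log transform with
#' left-censored imputation and mean-centring.
#'
#' @param run a raw [feature_run].
#' @param span loess span for [drift_correct_loess()].
#' @param seed imputation seed.
#' @param families compute family sums (requires annotations).
#' @return list with the processed `run` (log scale, centred, study samples
#'   only retained alongside QCs) and the filter `stats`.
#' @export
preprocess_ms <- function(run, span = 0.75, seed = 1L,
                          families = !is.null(run$features)) {
  corrected <- drift_correct_loess(run, span = span)
  filt <- apply_feature_filters(corrected)
  normed <- normalize_fecal_mass(filt$run)
  if (families) normed <- compute_ba_families(normed)
  list(run = log_impute_center(normed, seed = seed), stats = filt$stats)
}
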