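# Group-wise clinical moments used as generator defaults. They emulate the
# published characteristics of a 419-patient UDCA-treated PBC cohort
# (NR / R / R_BP columns): continuous variables as mean/sd, categorical as
# per-group probabilities.
.clinical_moments <- list(
  age        = list(mean = c(61.97, 64.47, 66.81), sd = c(10.69, 9.99, 7.70)),
  age_dx     = list(mean = c(52.29, 54.33, 53.93), sd = c(10.72, 9.99, 7.99)),
  bmi        = list(mean = c(27.62, 28.68, 27.01), sd = c(6.12, 6.23, 4.58)),
  albumin    = list(mean = c(40.17, 41.11, 38.62), sd = c(4.85, 4.24, 4.54)),
  bilirubin  = list(mean = c(13.07, 10.41, 13.12), sd = c(13.33, 5.53, 7.85)),
  alt        = list(mean = c(46.69, 28.89, 50.12), sd = c(34.04, 20.46, 28.13)),
  platelets  = list(mean = c(264.46, 250.17, 211.50), sd = c(115.78, 77.81, 81.51)),
  udca_dose  = list(mean = c(13.15, 12.30, 12.37), sd = c(3.58, 3.46, 4.19)),
  udca_years = list(mean = c(9.17, 9.44, 12.93), sd = c(6.09, 6.40, 6.60)),
  p_male         = c(0.099, 0.113, 0.125),
  p_ama_pos      = c(0.895, 0.926, 0.867),
  p_sequestrants = c(0.068, 0.028, 0.188),
  p_antibiotics  = c(0.215, 0.165, 0.250),
  p_apap         = c(0.052, 0.061, 0.062),
  p_statins      = c(0.141, 0.156, 0.188),
  p_ppi          = c(0.262, 0.349, 0.438),
  p_autoimmune   = c(0.209, 0.278, 0.375),
  p_celiac       = c(0.021, 0.009, 0.125),
  p_alcohol = rbind(abstinent = c(0.335, 0.335, 0.312),
                    moderate  = c(0.602, 0.604, 0.688),
                    excess    = c(0.063, 0.061, 0.000)),
  p_smoking = rbind(never   = c(0.403, 0.354, 0.312),
                    former  = c(0.513, 0.547, 0.625),
                    current = c(0.084, 0.099, 0.063)))

.default_effects_ms <- function(n_features) {
  k <- min(12L, n_features)
  data.frame(feature = seq_len(k),
             beta_R = seq(0.10, 0.30, length.out = k),
             beta_R_BP = -seq(0.10, 0.30, length.out = k))
}

.default_effects_taxa <- function(n_taxa) {
  k <- min(10L, n_taxa)
  data.frame(taxon = seq_len(k),
             beta_R = rep(c(0.5, -0.5), length.out = k),
             beta_R_BP = rep(c(-0.8, 0.8), length.out = k))
}

#' Simulation configuration for a synthetic UDCA-response cohort
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' defaults emulate the study conditions of a 419-patient UDCA-treated PBC
#' cohort: group fractions 45.6 / 50.6 / 3.8% (NR / R / R_BP), 20 recruiting
#' hospitals with assay-kit-specific ALP upper limits of normal, 56
#' annotated bile-acid LC-MS features with interspersed pooled-QC injections
#' and multiplicative run-order drift, planted group effects of |beta| =
#' 0.1-0.3 on the log-intensity scale, and a sparse overdispersed 9,865-taxon
#' count table calibrated so that roughly 4.5% of taxa are present in at
#' least 10% of samples.
#'
#' @param n_patients number of patients.
#' @param group_fractions proportions of NR, R, R_BP; must sum to 1.
#' @param n_hospitals number of recruiting hospitals.
#' @param uln_by_hospital ALP upper limit of normal (U/L) per hospital,
#'   recycled to `n_hospitals`.
#' @param n_features_ms number of LC-MS bile-acid features.
#' @param n_qc number of pooled QC injections (>= 2).
#' @param drift_amplitude fractional amplitude of the multiplicative
#'   run-order drift (0 disables drift).
#' @param ms_noise_sd analytic noise SD on the log-intensity scale.
#' @param censor_fraction fraction of intensities censored below the
#'   per-feature limit of detection.
#' @param effect_sizes_ms data frame (`feature`, `beta_R`, `beta_R_BP`) of
#'   planted log-scale group effects on LC-MS features.
#' @param n_taxa number of taxa (amplicon sequence variants).
#' @param sparsity target zero fraction of the count matrix, in \[0, 1).
#' @param effect_sizes_taxa data frame (`taxon`, `beta_R`, `beta_R_BP`) of
#'   planted log-fold-changes; taxa are indexed in decreasing base
#'   abundance, so low indices are prevalent.
#' @param structural_zeros optional data frame (`taxon`, `group`) of
#'   group-wise structural zeros to plant.
#' @param seed integer master seed; fully determines the cohort.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 419L,
                       group_fractions = c(NR = 0.456, R = 0.506, R_BP = 0.038),
                       n_hospitals = 20L,
                       uln_by_hospital = c(104, 115, 130),
                       n_features_ms = 56L,
                       n_qc = 40L,
                       drift_amplitude = 0.15,
                       ms_noise_sd = 0.2,
                       censor_fraction = 0.05,
                       effect_sizes_ms = .default_effects_ms(n_features_ms),
                       n_taxa = 9865L,
                       sparsity = 0.980,
                       effect_sizes_taxa = .default_effects_taxa(n_taxa),
                       structural_zeros = NULL,
                       seed = 1L) {
  counts <- c(n_patients = n_patients, n_hospitals = n_hospitals,
              n_features_ms = n_features_ms, n_qc = n_qc, n_taxa = n_taxa)
  if (!is_wholenumber(counts) || any(counts <= 0))
    stop("all counts must be positive integers")
  if (length(group_fractions) != 3 || any(group_fractions < 0) ||
      abs(sum(group_fractions) - 1) > 1e-8)
    stop("group_fractions must be 3 non-negative proportions summing to 1")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must lie in [0, 1)")
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop("censor_fraction must lie in [0, 1)")
  if (drift_amplitude < 0 || drift_amplitude >= 1)
    stop("drift_amplitude must lie in [0, 1)")
  if (!is.numeric(seed) || length(seed) != 1 || abs(seed) > 2^31 - 10)
    stop("seed must be a single integer below 2^31")
  check_positive(uln_by_hospital, "uln_by_hospital")
  structure(list(
    n_patients = as.integer(n_patients),
    group_fractions = stats::setNames(group_fractions, c("NR", "R", "R_BP")),
    n_hospitals = as.integer(n_hospitals),
    uln_by_hospital = rep_len(uln_by_hospital, n_hospitals),
    n_features_ms = as.integer(n_features_ms), n_qc = as.integer(n_qc),
    drift_amplitude = drift_amplitude, ms_noise_sd = ms_noise_sd,
    censor_fraction = censor_fraction, effect_sizes_ms = effect_sizes_ms,
    n_taxa = as.integer(n_taxa), sparsity = sparsity,
    effect_sizes_taxa = effect_sizes_taxa,
    structural_zeros = structural_zeros, seed = as.integer(seed)),
    class = "sim_config")
}

# largest-remainder apportionment of n into fractions
.apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  cnt <- as.integer(base)
  if (any(fractions > 0 & cnt == 0))
    stop("a group with positive requested fraction received zero patients; ",
         "increase n_patients")
  cnt
}

rtrunc_norm <- function(n, mean, sd, lower) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

#' Generate a synthetic clinical cohort
#'
#' Draws per-patient ALP values so that [classify_response()] recovers the
#' planted group label exactly, and clinical covariates from group-specific
#' distributions emulating the published cohort moments (age/BMI normal,
#' bilirubin/ALT log-normal, medications Bernoulli, smoking/alcohol 3-level
#' categorical, hospital uniform with its assay-specific ULN).
#'
#' @param config a [sim_config()].
#' @return data frame of clinical records; `attr(, "labels")` carries the
#'   planted response labels.
#' @export
generate_clinical <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  cnt <- .apportion(n, config$group_fractions)
  mom <- .clinical_moments

  with_seed(config$seed, {
    g <- sample(rep(factor(c("NR", "R", "R_BP"), levels = c("NR", "R", "R_BP")),
                    cnt))
    gi <- as.integer(g)
    hospital <- sample.int(config$n_hospitals, n, replace = TRUE)
    uln <- config$uln_by_hospital[hospital]

    # ALP consistent with the planted label, with safety margins off every
    # decision boundary (>40% fall, ULN, 1.67 x ULN)
    alp_post <- numeric(n); ratio <- numeric(n)
    i_nr <- which(gi == 1L); i_r <- which(gi == 2L); i_bp <- which(gi == 3L)
    alp_post[i_nr] <- uln[i_nr] * stats::runif(length(i_nr), 1.10, 2.80)
    ratio[i_nr] <- stats::runif(length(i_nr), 0.63, 0.97)
    norm_r <- stats::runif(length(i_r)) < 0.9   # most responders normalise
    alp_post[i_r] <- uln[i_r] * ifelse(norm_r,
                                       stats::runif(length(i_r), 0.55, 0.98),
                                       stats::runif(length(i_r), 1.05, 1.60))
    ratio[i_r] <- ifelse(norm_r, stats::runif(length(i_r), 0.35, 0.85),
                         stats::runif(length(i_r), 0.35, 0.58))
    alp_post[i_bp] <- uln[i_bp] * stats::runif(length(i_bp), 1.72, 3.20)
    ratio[i_bp] <- stats::runif(length(i_bp), 0.35, 0.58)
    alp_pre <- alp_post / ratio

    draw_norm <- function(mn) rtrunc_norm(n, mn$mean[gi], mn$sd[gi], 0.1)
    draw_lnorm <- function(mn) {
      cv <- mn$sd[gi] / mn$mean[gi]
      sl <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, log(mn$mean[gi]) - sl^2 / 2, sl)
    }
    draw_bin <- function(p) stats::runif(n) < p[gi]
    draw_cat <- function(pm) {
      u <- stats::runif(n)
      lv <- rownames(pm)
      idx <- integer(n)
      for (i in seq_len(n)) idx[i] <- findInterval(u[i], cumsum(pm[, gi[i]]),
                                                   left.open = TRUE) + 1L
      factor(lv[pmin(idx, nrow(pm))], levels = lv)
    }

    sex <- factor(ifelse(draw_bin(mom$p_male), "male", "female"),
                  levels = c("female", "male"))
    bmi <- rtrunc_norm(n, mom$bmi$mean[gi], mom$bmi$sd[gi], 15)
    height <- stats::rnorm(n, ifelse(sex == "male", 1.76, 1.63), 0.07)
    udca_years <- 1 + stats::rgamma(
      n, shape = ((mom$udca_years$mean[gi] - 1) / mom$udca_years$sd[gi])^2,
      rate = (mom$udca_years$mean[gi] - 1) / mom$udca_years$sd[gi]^2)

    rec <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      hospital = factor(sprintf("H%02d", hospital),
                        levels = sprintf("H%02d", seq_len(config$n_hospitals))),
      uln_alp = uln,
      sex = sex,
      age = draw_norm(mom$age),
      age_at_diagnosis = draw_norm(mom$age_dx),
      bmi = bmi,
      weight = bmi * height^2,
      ama = draw_bin(mom$p_ama_pos),
      alp_pre = alp_pre, alp_post = alp_post,
      bilirubin = draw_lnorm(mom$bilirubin),
      albumin = draw_norm(mom$albumin),
      alt = draw_lnorm(mom$alt),
      platelets = rtrunc_norm(n, mom$platelets$mean[gi], mom$platelets$sd[gi], 20),
      udca_dose = rtrunc_norm(n, mom$udca_dose$mean[gi], mom$udca_dose$sd[gi], 3),
      udca_years = udca_years,
      sequestrants = draw_bin(mom$p_sequestrants),
      antibiotics = draw_bin(mom$p_antibiotics),
      apap = draw_bin(mom$p_apap),
      statins = draw_bin(mom$p_statins),
      ppi = draw_bin(mom$p_ppi),
      alcohol = draw_cat(mom$p_alcohol),
      smoking = draw_cat(mom$p_smoking),
      autoimmune_any = draw_bin(mom$p_autoimmune),
      celiac = draw_bin(mom$p_celiac),
      stringsAsFactors = FALSE)
    attr(rec, "labels") <- g
    rec
  })
}

# smooth cubic drift profile in normalised run order u in [0, 1],
# scaled to max |.| = 1 so drift_amplitude is the exact fractional amplitude
.drift_profile <- function(u) {
  q <- -(2 * u - 1) + 0.35 * (2 * u - 1)^3
  q / 0.65
}

#' Generate a synthetic LC-MS bile-acid feature run
#'
#' Log-normal feature intensities with planted per-group effects on the log
#' scale, a pooled-QC mean profile, a smooth multiplicative run-order drift
#' shared by study and QC injections, and left-censoring below a per-feature
#' limit of detection. Features carry synthetic bile-acid annotations
#' (compound x conjugation class) so that family sums can be exercised.
#'
#' @param config a [sim_config()].
#' @param clinical output of [generate_clinical()].
#' @return A [feature_run].
#' @export
generate_metabolome <- function(config, clinical) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(clinical))
  if (config$n_qc < 2) stop("n_qc must be >= 2 to fit a drift curve")
  labels <- attr(clinical, "labels")
  if (is.null(labels)) labels <- classify_response(clinical)
  n <- nrow(clinical); nf <- config$n_features_ms
  total <- n + config$n_qc
  if (config$n_qc > total / 2) stop("too many QC samples for the run length")

  with_seed(config$seed + 1L, {
    qc_pos <- round(seq(1, total, length.out = config$n_qc))
    if (anyDuplicated(qc_pos)) stop("QC positions collide; reduce n_qc")
    study_pos <- sample(setdiff(seq_len(total), qc_pos))

    bas <- c("CA", "CDCA", "DCA", "LCA", "UDCA", "HDCA", "HCA", "12-DHCA",
             "7-DHCA", "isoDCA", "12-epiCA", "7,12-DKCA", "isoLCA", "MCA",
             "12-oxoLCA", "3-DHCA", "alloCA", "NorCA", "UCA")
    conj <- c("unconjugated", "glyco", "tauro")
    features <- data.frame(
      feature_id = sprintf("BA%03d", seq_len(nf)),
      ba = bas[((seq_len(nf) - 1) %/% 3) %% length(bas) + 1],
      conjugation = conj[(seq_len(nf) - 1) %% 3 + 1],
      stringsAsFactors = FALSE)

    mu <- stats::rnorm(nf, 11.5, 1.2)
    beta <- matrix(0, nf, 3, dimnames = list(NULL, c("NR", "R", "R_BP")))
    eff <- config$effect_sizes_ms
    if (!is.null(eff) && nrow(eff)) {
      beta[eff$feature, "R"] <- eff$beta_R
      beta[eff$feature, "R_BP"] <- eff$beta_R_BP
    }
    s_i <- stats::rnorm(n, 0, 0.15)

    logint_study <- matrix(mu, n, nf, byrow = TRUE) +
      t(beta)[as.integer(labels), , drop = FALSE] + s_i +
      matrix(stats::rnorm(n * nf, 0, config$ms_noise_sd), n, nf)
    logint_qc <- matrix(mu, config$n_qc, nf, byrow = TRUE) +
      matrix(stats::rnorm(config$n_qc * nf, 0, config$ms_noise_sd),
             config$n_qc, nf)

    run_order <- c(study_pos, qc_pos)
    u <- (run_order - 1) / (total - 1)
    drift <- 1 + config$drift_amplitude * .drift_profile(u)
    intens <- exp(rbind(logint_study, logint_qc)) * drift

    samples <- data.frame(
      sample_id = c(clinical$patient_id, sprintf("QC%03d", seq_len(config$n_qc))),
      run_order = run_order,
      role = rep(c("study", "QC"), c(n, config$n_qc)),
      fecal_mass = c(stats::runif(n, 40, 150), rep(NA_real_, config$n_qc)),
      stringsAsFactors = FALSE)
    rownames(intens) <- samples$sample_id
    colnames(intens) <- features$feature_id

    if (config$censor_fraction > 0) {
      lod <- apply(intens, 2, stats::quantile, probs = config$censor_fraction)
      intens[sweep(intens, 2, lod, "<")] <- NA_real_
    } else {
      lod <- apply(intens, 2, min) * 0.5
    }

    feature_run(samples = samples, intensities = intens, lod = lod,
                features = features, matrix_type = "fecal")
  })
}

#' Generate a synthetic microbiome count table and tree
#'
#' Sparse overdispersed counts from a log-normal-Poisson model: heavy-tailed
#' taxon base abundances (so that only a small fraction of taxa are
#' prevalent), log-normal per-sample library sizes, cell-level log-normal
#' overdispersion, planted per-group log-fold-changes, optional structural
#' zeros, and a calibrated global scaling that hits the configured target
#' zero fraction. A random bifurcating tree with exponential branch lengths
#' is drawn over the taxa.
#'
#' @param config a [sim_config()].
#' @param clinical output of [generate_clinical()].
#' @return list with elements `counts` (a [count_table]) and `tree`
#'   (an `ape::phylo`).
#' @export
generate_microbiome <- function(config, clinical) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(clinical))
  if (config$sparsity >= 1) stop("sparsity must be < 1")
  labels <- attr(clinical, "labels")
  if (is.null(labels)) labels <- classify_response(clinical)
  n <- nrow(clinical); nt <- config$n_taxa
  taxa <- sprintf("ASV%05d", seq_len(nt))

  with_seed(config$seed + 2L, {
    a <- sort(stats::rnorm(nt, 0, 3), decreasing = TRUE)
    p <- exp(a - max(a)); p <- p / sum(p)
    libsize <- stats::rlnorm(n, log(2e4), 0.35)
    loglam <- log(libsize) + matrix(log(p), n, nt, byrow = TRUE) +
      matrix(stats::rnorm(n * nt, 0, 1), n, nt)

    eff <- config$effect_sizes_taxa
    if (!is.null(eff) && nrow(eff)) {
      b <- matrix(0, nt, 3, dimnames = list(NULL, c("NR", "R", "R_BP")))
      b[eff$taxon, "R"] <- eff$beta_R
      b[eff$taxon, "R_BP"] <- eff$beta_R_BP
      loglam <- loglam + t(b)[as.integer(labels), , drop = FALSE]
    }
    lam <- exp(loglam)
    if (!is.null(config$structural_zeros))
      for (k in seq_len(nrow(config$structural_zeros)))
        lam[labels == config$structural_zeros$group[k],
            config$structural_zeros$taxon[k]] <- 0

    # global scaling calibrated so the expected zero fraction of the
    # Poisson layer matches the configured sparsity
    zf <- function(logf) mean(exp(-exp(logf) * lam)) - config$sparsity
    logf <- stats::uniroot(zf, c(-25, 25), tol = 1e-4)$root
    cnt <- matrix(stats::rpois(n * nt, exp(logf) * lam), n, nt,
                  dimnames = list(clinical$patient_id, taxa))
    # guarantee a positive library for every sample (vanishingly rare at
    # realistic sparsity, but possible in tiny test configurations)
    empty <- rowSums(cnt) == 0
    cnt[empty, 1L] <- 1L

    tree <- ape::rtree(nt, br = stats::rexp)
    tree$tip.label <- taxa[as.integer(sub("^t", "", tree$tip.label))]
    list(counts = count_table(cnt), tree = tree)
  })
}

#' Generate a complete synthetic cohort bundle
#'
#' Clinical records, LC-MS feature run, microbiome counts with phylogeny,
#' and the ground truth (planted labels and effects) needed to validate
#' every downstream stage.
#'
#' @param config a [sim_config()].
#' @return list of class `cohort_bundle` with elements `clinical`, `ms_run`,
#'   `counts`, `tree`, `truth`, `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  clinical <- generate_clinical(config)
  ms_run <- generate_metabolome(config, clinical)
  micro <- generate_microbiome(config, clinical)
  structure(list(
    clinical = clinical, ms_run = ms_run,
    counts = micro$counts, tree = micro$tree,
    truth = list(labels = attr(clinical, "labels"),
                 effect_sizes_ms = config$effect_sizes_ms,
                 effect_sizes_taxa = config$effect_sizes_taxa,
                 structural_zeros = config$structural_zeros),
    config = config), class = "cohort_bundle")
}
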