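#' Simulate true methylation fractions with genetic and covariate structure
#'
#' Baseline per-CpG methylation is drawn from a three-class mixture (high
#' >0.8 / intermediate / low <0.2) with the configured weights; CpH baselines
#' are low (Beta(1, 19), generally unmethylated). A configured fraction of
#' SNPs carries a cis effect: each shifts methylation additively by
#' `dosage x effect` at every CpG inside a contiguous bp window (Gamma-
#' distributed width around `effect_width_mean`, centred on the SNP). Effect
#' direction points away from the prevailing boundary of the window (windows
#' dominated by highly methylated sites lose methylation per alternate
#' allele), keeping the additive model inside [0, 1] for typical effects;
#' residual excursions are clipped and recorded. CpH sites inside a window
#' respond sparsely with large effects. Covariate structure (batch offsets,
#' neuronal-fraction slopes, predominantly positive age slopes) and iid
#' biological noise complete the true fractions.
#'
#' @param genotypes A `genotype_set` from [simulate_genotypes()].
#' @param config The same [sim_config()] used for the genotypes.
#' @return A list with `fractions` (sites x samples true methylation),
#'   `sites` (tibble chrom/pos/context), `covariates` (tibble, one row per
#'   sample), and `truth` (a `truth_table`).
#' @export
simulate_methylome <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_set"))
  if (length(genotypes$samples) != config$n_samples) {
    rlang::abort("genotype sample count does not match config$n_samples")
  }
  set.seed(config$seed + 1L)
  n <- config$n_samples

  sites <- sim_sites(config)
  ns <- nrow(sites)
  is_cpg <- sites$context == "CpG"

  baseline <- numeric(ns)
  cls <- sample.int(3L, sum(is_cpg), replace = TRUE, prob = config$baseline_mixture)
  cpg_base <- numeric(sum(is_cpg))
  cpg_base[cls == 1] <- 0.8 + 0.2 * stats::rbeta(sum(cls == 1), 5, 2)
  cpg_base[cls == 2] <- 0.2 + 0.6 * stats::rbeta(sum(cls == 2), 2, 2)
  cpg_base[cls == 3] <- 0.2 * stats::rbeta(sum(cls == 3), 2, 5)
  baseline[is_cpg] <- cpg_base
  baseline[!is_cpg] <- stats::rbeta(sum(!is_cpg), 1, 19)

  covariates <- sim_covariates(config)

  frac <- matrix(rep(baseline, n), ns, n)

  # --- genetic effects ---------------------------------------------------
  n_eff <- round(config$meqtl_fraction * config$n_snps)
  eff_idx <- sort(sample.int(config$n_snps, n_eff))
  snp_effects <- tibble::tibble(
    snp_id = character(0), effect = numeric(0),
    win_start = numeric(0), win_end = numeric(0), truncated = logical(0)
  )
  pair_effects <- list()
  if (n_eff > 0) {
    widths <- stats::rgamma(n_eff, shape = 3, scale = config$effect_width_mean / 3)
    snp_pos <- genotypes$snps$pos[eff_idx]
    ws <- pmax(1, snp_pos - widths / 2)
    we <- pmin(config$chrom_length, snp_pos + widths / 2)
    truncated <- (snp_pos - widths / 2 < 1) | (snp_pos + widths / 2 > config$chrom_length)
    if (any(truncated)) {
      rlang::warn(sprintf("%d effect window(s) truncated at chromosome ends", sum(truncated)))
    }
    mag_cpg <- stats::rgamma(n_eff, shape = 2, scale = config$effect_mean_cpg / 2)
    for (k in seq_len(n_eff)) {
      in_win <- which(sites$pos >= ws[k] & sites$pos <= we[k])
      cpg_in <- in_win[is_cpg[in_win]]
      cph_in <- in_win[!is_cpg[in_win]]
      sgn <- if (length(cpg_in) && mean(baseline[cpg_in]) > 0.5) -1 else 1
      eff <- sgn * mag_cpg[k]
      dos <- genotypes$dosage[, eff_idx[k]]
      if (length(cpg_in)) {
        frac[cpg_in, ] <- frac[cpg_in, ] + outer(rep(eff, length(cpg_in)), dos)
        pair_effects[[length(pair_effects) + 1L]] <- tibble::tibble(
          snp_id = genotypes$snps$snp_id[eff_idx[k]],
          site_idx = cpg_in, context = "CpG", delta = eff
        )
      }
      if (length(cph_in)) {
        hit <- cph_in[stats::runif(length(cph_in)) < config$cph_effect_fraction]
        if (length(hit)) {
          cph_eff <- stats::rgamma(length(hit), shape = 2,
                                   scale = config$effect_mean_cph / 2)
          frac[hit, ] <- frac[hit, ] + outer(cph_eff, dos)
          pair_effects[[length(pair_effects) + 1L]] <- tibble::tibble(
            snp_id = genotypes$snps$snp_id[eff_idx[k]],
            site_idx = hit, context = "CpH", delta = cph_eff
          )
        }
      }
      snp_effects <- dplyr::bind_rows(snp_effects, tibble::tibble(
        snp_id = genotypes$snps$snp_id[eff_idx[k]], effect = eff,
        win_start = ws[k], win_end = we[k], truncated = truncated[k]
      ))
    }
  }

  # --- covariate structure ----------------------------------------------
  n_age <- round(config$age_site_fraction * ns)
  age_sites <- sort(sample.int(ns, n_age))
  age_slope <- numeric(ns)
  if (n_age > 0) {
    up <- stats::runif(n_age) < config$age_increase_fraction
    age_slope[age_sites] <- ifelse(up, 1, -1) *
      abs(stats::rnorm(n_age, 0, config$age_slope_sd))
  }
  batch_sd <- config$noise_sd *
    sqrt(config$batch_var_share / (1 - config$batch_var_share) / 0.25)
  batch_beta <- stats::rnorm(ns, 0, batch_sd)
  neuro_beta <- stats::rnorm(ns, 0, config$neuronal_slope_sd)

  age_c <- (covariates$age - mean(covariates$age)) / 10  # slopes are per decade
  batch_ind <- as.numeric(covariates$batch == "B2")
  neuro_c <- covariates$neuronal_fraction - mean(covariates$neuronal_fraction)

  frac <- frac + outer(age_slope, age_c) + outer(batch_beta, batch_ind) +
    outer(neuro_beta, neuro_c)
  # regional co-methylation: one noise draw per (block, sample), shared by
  # all sites in the block, plus site-level iid noise
  if (config$region_noise_sd > 0) {
    block <- as.integer(sites$pos %/% config$region_block_bp) + 1L
    bn <- matrix(stats::rnorm(max(block) * n, 0, config$region_noise_sd),
                 max(block), n)
    frac <- frac + bn[block, , drop = FALSE]
  }
  frac <- frac + matrix(stats::rnorm(ns * n, 0, config$noise_sd), ns, n)

  clipped <- frac < 0 | frac > 1
  frac[frac < 0] <- 0
  frac[frac > 1] <- 1

  truth <- structure(list(
    snp_effects = snp_effects,
    pair_effects = if (length(pair_effects)) dplyr::bind_rows(pair_effects)
                   else tibble::tibble(snp_id = character(0), site_idx = integer(0),
                                       context = character(0), delta = numeric(0)),
    site_truth = tibble::tibble(
      site_idx = seq_len(ns), context = sites$context, baseline = baseline,
      age_slope = age_slope, batch_beta = batch_beta, neuro_beta = neuro_beta
    ),
    clipped_per_site = rowSums(clipped),
    mediation = NULL
  ), class = "truth_table")

  rownames(frac) <- NULL
  colnames(frac) <- genotypes$samples
  list(fractions = frac, sites = sites, covariates = covariates, truth = truth)
}

sim_sites <- function(config) {
  pos <- sort(sample.int(config$chrom_length, config$n_cpg + config$n_cph))
  ctx <- rep("CpG", length(pos))
  ctx[sample.int(length(pos), config$n_cph)] <- "CpH"
  tibble::tibble(chrom = "chrSim", pos = pos, context = ctx, strand = "+")
}

sim_covariates <- function(config) {
  n <- config$n_samples
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    age = stats::runif(n, 18, 96),
    sex = sample(c("F", "M"), n, replace = TRUE),
    diagnosis = sample(c("Control", "Case"), n, replace = TRUE),
    batch = sample(c("B1", "B2"), n, replace = TRUE),
    neuronal_fraction = 0.2 + 0.2 * stats::rbeta(n, 2, 2),
    mds1 = stats::rnorm(n, 0, 0.02),
    mds2 = stats::rnorm(n, 0, 0.02),
    mds3 = stats::rnorm(n, 0, 0.02)
  )
}

#' Draw sequencing read counts over true methylation fractions
#'
#' Coverage per site/sample is zero-truncated Poisson with (truncated) mean
#' `config$mean_coverage`; the methylated count is Binomial(coverage, true
#' fraction).
#'
#' @param true_fractions Sites x samples matrix of fractions in [0, 1].
#' @param sites Site tibble matching the rows.
#' @param config A [sim_config()].
#' @return A [methylome()] with counts (no smoothing yet).
#' @export
sample_read_counts <- function(true_fractions, sites, config) {
  assert_fraction(true_fractions, "true_fractions")
  set.seed(config$seed + 2L)
  ns <- nrow(true_fractions)
  n <- ncol(true_fractions)
  lambda <- ztpois_lambda(config$mean_coverage)
  cov <- matrix(rztpois(ns * n, lambda), ns, n)
  meth <- matrix(stats::rbinom(ns * n, as.vector(cov), as.vector(true_fractions)),
                 ns, n)
  samples <- colnames(true_fractions) %||% sprintf("S%03d", seq_len(n))
  methylome(sites, meth, cov, samples)
}
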