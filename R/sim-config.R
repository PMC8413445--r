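#' Simulation configuration for synthetic WGBS + genotype cohorts
#'
#' Bundles every knob of the synthetic-data generator. Defaults reproduce the
#' statistical structure of deep WGBS brain cohorts: bimodal CpG methylation
#' with 78% of sites highly (>80%) methylated and 8% lowly (<20%) methylated,
#' mean sequencing coverage of 17.3 reads per site, additive cis SNP effects
#' of mean 2.6% methylation per allele spread over windows of mean 14.5 kb,
#' sparse large (27% per allele) CpH effects, and covariate structure from
#' batch, neuronal fraction and age (94% of age-associated sites gaining
#' methylation with age).
#'
#' @param n_samples Number of donors (>= 4).
#' @param n_snps Number of biallelic SNPs.
#' @param n_cpg,n_cph Number of CpG / CpH sites.
#' @param chrom_length Length of the single synthetic chromosome, bp.
#' @param maf_range Range the per-SNP minor allele frequency is drawn from.
#' @param ld_block_size SNPs per correlated LD block.
#' @param ld_rho Latent AR(1) correlation between adjacent SNPs in a block;
#'   controls within-block r-squared.
#' @param mean_coverage Mean of the zero-truncated Poisson read coverage.
#' @param baseline_mixture Weights of the high (>0.8), intermediate and low
#'   (<0.2) baseline methylation classes; must sum to 1.
#' @param meqtl_fraction Fraction of SNPs carrying a methylation effect.
#' @param effect_mean_cpg Mean absolute per-allele CpG effect (methylation
#'   fraction units).
#' @param effect_mean_cph Mean absolute per-allele CpH effect.
#' @param effect_width_mean Mean bp width of a SNP's effect window.
#' @param cph_effect_fraction Fraction of CpH sites inside an effect window
#'   that actually respond (CpH genetic control is sparse).
#' @param age_site_fraction Fraction of CpG sites with an age trend.
#' @param age_increase_fraction Fraction of age-associated sites whose
#'   methylation increases with age.
#' @param age_slope_sd SD of the per-decade age slope at age-associated sites.
#' @param batch_var_share Share of non-genetic per-site variance attributable
#'   to batch.
#' @param neuronal_slope_sd SD of per-site slopes on neuronal fraction.
#' @param noise_sd SD of site-level iid biological noise added to true
#'   fractions.
#' @param region_noise_sd SD of sample-by-region co-methylation noise shared
#'   by all sites in a `region_block_bp` block (WGBS methylation varies
#'   coherently over regional domains, not site-by-site).
#' @param region_block_bp Length of a co-methylation block in bp.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 20, n_snps = 50, n_cpg = 500, seed = 1)
sim_config <- function(n_samples = 165,
                       n_snps = 500,
                       n_cpg = 5000,
                       n_cph = 500,
                       chrom_length = 5e5,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_rho = 0.9,
                       mean_coverage = 17.3,
                       baseline_mixture = c(high = 0.78, mid = 0.14, low = 0.08),
                       meqtl_fraction = 0.2,
                       effect_mean_cpg = 0.026,
                       effect_mean_cph = 0.27,
                       effect_width_mean = 14500,
                       cph_effect_fraction = 0.1,
                       age_site_fraction = 0.1,
                       age_increase_fraction = 0.94,
                       age_slope_sd = 0.005,
                       batch_var_share = 0.10,
                       neuronal_slope_sd = 0.02,
                       noise_sd = 0.01,
                       region_noise_sd = 0.015,
                       region_block_bp = 20000,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    n_cpg = as.integer(n_cpg), n_cph = as.integer(n_cph),
    chrom_length = as.numeric(chrom_length),
    maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size), ld_rho = as.numeric(ld_rho),
    mean_coverage = as.numeric(mean_coverage),
    baseline_mixture = as.numeric(baseline_mixture),
    meqtl_fraction = as.numeric(meqtl_fraction),
    effect_mean_cpg = as.numeric(effect_mean_cpg),
    effect_mean_cph = as.numeric(effect_mean_cph),
    effect_width_mean = as.numeric(effect_width_mean),
    cph_effect_fraction = as.numeric(cph_effect_fraction),
    age_site_fraction = as.numeric(age_site_fraction),
    age_increase_fraction = as.numeric(age_increase_fraction),
    age_slope_sd = as.numeric(age_slope_sd),
    batch_var_share = as.numeric(batch_var_share),
    neuronal_slope_sd = as.numeric(neuronal_slope_sd),
    noise_sd = as.numeric(noise_sd),
    region_noise_sd = as.numeric(region_noise_sd),
    region_block_bp = as.numeric(region_block_bp),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 4) rlang::abort("`n_samples` must be >= 4.")
  if (cfg$n_snps < 1) rlang::abort("`n_snps` must be >= 1.")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2]) {
    rlang::abort("`maf_range` must be an increasing pair within (0, 0.5].")
  }
  if (length(cfg$baseline_mixture) != 3 ||
      abs(sum(cfg$baseline_mixture) - 1) > 1e-8 ||
      any(cfg$baseline_mixture < 0)) {
    rlang::abort("`baseline_mixture` must be three non-negative weights summing to 1.")
  }
  for (nm in c("meqtl_fraction", "age_site_fraction", "age_increase_fraction",
               "batch_var_share", "cph_effect_fraction")) {
    assert_fraction(cfg[[nm]], nm)
  }
  if (cfg$mean_coverage <= 1) rlang::abort("`mean_coverage` must exceed 1.")
  if (cfg$chrom_length <= 4e4) {
    rlang::abort("`chrom_length` must exceed the scan windows used downstream (40 kb).")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d samples, %d SNPs, %d CpG + %d CpH sites on %.3g bp\n",
              x$n_samples, x$n_snps, x$n_cpg, x$n_cph, x$chrom_length))
  cat(sprintf("  coverage %.1fx, meQTL fraction %.2f, CpG effect %.3f/allele, seed %d\n",
              x$mean_coverage, x$meqtl_fraction, x$effect_mean_cpg, x$seed))
  invisible(x)
}
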