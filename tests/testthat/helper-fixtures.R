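# Shared small fixtures, built once when the helpers are sourced.

# A small cohort used by several module tests: 60 samples, 60 SNPs,
# 600 CpG + 60 CpH sites on a 60 kb chromosome.
tiny_config <- function(seed = 11, ...) {
  sim_config(n_samples = 60, n_snps = 60, n_cpg = 600, n_cph = 60,
             chrom_length = 60000, seed = seed, ...)
}

tiny_cohort <- local({
  cfg <- tiny_config()
  geno <- simulate_genotypes(cfg)
  sim <- suppressWarnings(simulate_methylome(geno, cfg))
  meth <- sample_read_counts(sim$fractions, sim$sites, cfg)
  meth <- smooth_methylome(meth)
  list(cfg = cfg, geno = geno, sim = sim, meth = meth)
})

# Build a methylome directly from a smoothed matrix (counts are a plausible
# rounding of the fractions so the container invariants hold).
methylome_from_smoothed <- function(values, positions = NULL,
                                    chrom = "chrSim", context = "CpG") {
  values <- as.matrix(values)
  ns <- nrow(values)
  if (is.null(positions)) positions <- seq_len(ns) * 100
  cov <- matrix(10L, ns, ncol(values))
  meth <- matrix(as.integer(round(values * 10)), ns, ncol(values))
  methylome(
    tibble::tibble(chrom = chrom, pos = positions, context = context),
    meth, cov, sprintf("P%02d", seq_len(ncol(values))), smoothed = values
  )
}

# Genotype set built directly from a dosage matrix (samples x SNPs).
genotypes_from_dosage <- function(dosage, pos = NULL, chrom = "chrSim") {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  samples <- rownames(dosage)
  if (is.null(samples)) samples <- sprintf("P%02d", seq_len(nrow(dosage)))
  rownames(dosage) <- samples
  snp_id <- sprintf("s%03d", seq_len(m))
  colnames(dosage) <- snp_id
  af <- colMeans(dosage, na.rm = TRUE) / 2
  wgbsqtl:::new_genotype_set(
    snps = tibble::tibble(snp_id = snp_id,
                          chrom = rep_len(chrom, m), pos = pos,
                          maf = pmin(af, 1 - af), missingness = 0,
                          hwe_p = NA_real_),
    dosage = dosage, samples = samples
  )
}
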