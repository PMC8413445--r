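test_that("a MAF-0.5 SNP has mean dosage 1 under Hardy-Weinberg", {
  cfg <- sim_config(n_samples = 10000, n_snps = 1, n_cpg = 10, n_cph = 0,
                    chrom_length = 1e5, maf_range = c(0.5, 0.5), seed = 3)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosage %in% 0:2))
  expect_lt(abs(mean(g$dosage) - 1), 0.03)
})

test_that("genotype class counts follow Hardy-Weinberg proportions", {
  cfg <- sim_config(n_samples = 5000, n_snps = 2000, n_cpg = 10, n_cph = 0,
                    chrom_length = 4e6, maf_range = c(0.2, 0.2), seed = 4)
  g <- simulate_genotypes(cfg)
  n0 <- colSums(g$dosage == 0)
  n1 <- colSums(g$dosage == 1)
  n2 <- colSums(g$dosage == 2)
  hwe_p <- hwe_test(n0, n1, n2)
  # per-SNP goodness-of-fit p-values should look uniform; SNPs within an LD
  # block are correlated, so the Monte-Carlo SE is clustered at block level
  reject <- hwe_p < 0.05
  block <- ceiling(seq_along(reject) / cfg$ld_block_size)
  block_rate <- tapply(reject, block, mean)
  mc_se <- sd(block_rate) / sqrt(length(block_rate))
  expect_lt(abs(mean(reject) - 0.05), 3 * mc_se + 1e-9)
  # marginal class proportions match (p^2, 2pq, q^2) at p = 0.8
  expect_lt(abs(mean(n1) / 5000 - 2 * 0.8 * 0.2), 0.005)
})

test_that("no simulated SNP is assigned a MAF below the configured floor", {
  g <- tiny_cohort$geno
  expect_true(all(g$snps$maf >= tiny_cohort$cfg$maf_range[1]))
  expect_true(all(diff(g$snps$pos) > 0))
})

test_that("degenerate configs are rejected", {
  expect_error(sim_config(n_samples = 1), "n_samples")
  expect_error(sim_config(baseline_mixture = c(0.5, 0.5, 0.5)), "mixture")
})

test_that("without injected effects no dosage-methylation correlation arises", {
  cfg <- sim_config(n_samples = 100, n_snps = 40, n_cpg = 400, n_cph = 0,
                    chrom_length = 1e5, meqtl_fraction = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  sim <- simulate_methylome(g, cfg)
  ok <- apply(sim$fractions, 1, sd) > 0
  r <- abs(cor(t(sim$fractions[ok, ]), g$dosage))
  # Bonferroni-style chance bound on the maximum |r| over all pairs
  n_pairs <- length(r)
  bound <- tanh(qnorm(1 - 0.001 / (2 * n_pairs)) / sqrt(cfg$n_samples - 3))
  expect_lt(max(r), bound)
  expect_equal(nrow(sim$truth$pair_effects), 0)
})

test_that("the default baseline mixture yields 78% highly methylated CpGs", {
  cfg <- sim_config(seed = 6)
  g <- simulate_genotypes(cfg)
  sim <- suppressWarnings(simulate_methylome(g, cfg))
  st <- sim$truth$site_truth
  frac_high <- mean(st$baseline[st$context == "CpG"] > 0.8)
  expect_lt(abs(frac_high - 0.78), 0.02)
})

test_that("a single noiseless effect shifts group means by exactly the effect", {
  cfg <- sim_config(n_samples = 200, n_snps = 1, n_cpg = 200, n_cph = 0,
                    chrom_length = 1e5, maf_range = c(0.5, 0.5),
                    meqtl_fraction = 1, noise_sd = 0, region_noise_sd = 0,
                    age_site_fraction = 0, neuronal_slope_sd = 0,
                    batch_var_share = 0, seed = 7)
  g <- simulate_genotypes(cfg)
  sim <- suppressWarnings(simulate_methylome(g, cfg))
  pe <- sim$truth$pair_effects
  expect_gt(nrow(pe), 0)
  unclipped <- pe$site_idx[sim$truth$clipped_per_site[pe$site_idx] == 0]
  expect_gt(length(unclipped), 0)
  dos <- g$dosage[, 1]
  for (i in unclipped[seq_len(min(5, length(unclipped)))] ) {
    d02 <- mean(sim$fractions[i, dos == 2]) - mean(sim$fractions[i, dos == 0])
    expect_equal(d02 / 2, pe$delta[pe$site_idx == i][1], tolerance = 1e-12)
  }
})

test_that("every recorded effect pair lies inside its SNP's effect window", {
  sim <- tiny_cohort$sim
  pe <- sim$truth$pair_effects
  win <- sim$truth$snp_effects
  pos <- sim$sites$pos[pe$site_idx]
  i <- match(pe$snp_id, win$snp_id)
  expect_true(all(pos >= win$win_start[i] & pos <= win$win_end[i]))
})

test_that("read counts honour the coverage target and the binomial mean", {
  # true fraction 0 -> methylated counts identically 0
  cfg0 <- tiny_config(seed = 8)
  sites0 <- tibble::tibble(chrom = "chrSim", pos = 1:50, context = "CpG")
  f0 <- matrix(0, 50, 60)
  m0 <- sample_read_counts(f0, sites0, cfg0)
  expect_true(all(m0$methylated == 0))
  expect_true(all(m0$coverage >= 1))

  # mean coverage 17.3 over 1e5 site-samples
  cfg <- sim_config(n_samples = 100, n_cpg = 1000, n_cph = 0,
                    chrom_length = 100000, seed = 9)
  sites <- tibble::tibble(chrom = "chrSim", pos = seq_len(1000) * 100,
                          context = "CpG")
  f <- matrix(0.4, 1000, 100)
  m <- sample_read_counts(f, sites, cfg)
  expect_lt(abs(mean(m$coverage) - 17.3), 0.1)

  # binomial mean at p = 0.4 within 3 Monte-Carlo SE
  fr <- mean(m$methylated / m$coverage)
  se <- sd(as.vector(m$methylated / m$coverage)) / sqrt(length(m$coverage))
  expect_lt(abs(fr - 0.4), 3 * se)
  expect_true(all(m$methylated <= m$coverage))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 10)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  s1 <- suppressWarnings(simulate_methylome(g1, cfg))
  s2 <- suppressWarnings(simulate_methylome(g2, cfg))
  expect_identical(s1$fractions, s2$fractions)
  m1 <- sample_read_counts(s1$fractions, s1$sites, cfg)
  m2 <- sample_read_counts(s2$fractions, s2$sites, cfg)
  expect_identical(m1$methylated, m2$methylated)
})

test_that("simulated GWAS chi-squares follow the stratified model mean", {
  co <- tiny_cohort
  # null model: all tau = 0 -> mean chi-square near 1
  eg0 <- suppressWarnings(simulate_expression_and_gwas(co$geno, co$sim, co$cfg))
  expect_lt(abs(mean(eg0$gwas$chisq) - 1), 3 * sqrt(2 / nrow(eg0$gwas)))

  # nonzero tau on one annotation raises the mean by the analytic amount
  ann <- cbind(full_genome = rep(TRUE, 60),
               hot = seq_len(60) <= 20)
  tau <- c(0, 4e-4)
  eg <- simulate_expression_and_gwas(co$geno, co$sim, co$cfg,
                                     annotations = ann, tau = tau,
                                     n_gwas = 5e4, ld_window = 5000)
  lmat <- as.matrix(eg$ld[, c("l_full_genome", "l_hot")])
  ev <- 1 + 5e4 * as.vector(lmat %*% tau)
  mc_se <- sqrt(2 * sum(ev^2)) / length(ev)
  expect_lt(abs(mean(eg$gwas$chisq) - mean(ev)), 3 * mc_se)
  expect_gt(mean(eg$gwas$chisq[ann[, "hot"]]),
            mean(eg$gwas$chisq[!ann[, "hot"]]))
})

test_that("mediation triplets require recorded meQTL effects", {
  cfg <- sim_config(n_samples = 60, n_snps = 20, n_cpg = 100, n_cph = 0,
                    chrom_length = 1e5, meqtl_fraction = 0, seed = 12)
  g <- simulate_genotypes(cfg)
  sim <- simulate_methylome(g, cfg)
  expect_error(
    simulate_expression_and_gwas(g, sim, cfg, mediation_props = 0.5),
    "no meQTL effects")
})

test_that("a fully mediated triplet attenuates the genotype coefficient to zero", {
  co <- tiny_cohort
  eg <- suppressWarnings(simulate_expression_and_gwas(co$geno, co$sim, co$cfg,
                                                    mediation_props = c(1, 0)))
  med <- eg$truth$mediation
  for (i in 1:2) {
    fit <- mediation_fit(eg$expression[i, ],
                         co$geno$dosage[, med$snp_id[i]],
                         co$sim$fractions[med$site_idx[i], ])
    expect_lt(abs((1 - fit$prop_retained) - med$true_prop_mediated[i]), 0.2)
  }
})
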