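test_that("cis pair enumeration is inclusive at the window boundary", {
  g <- genotypes_from_dosage(matrix(c(0L, 1L, 2L, 1L), 4, 1), pos = 100000)
  sites <- tibble::tibble(chrom = "chrSim", pos = c(80000, 120000, 120001),
                          context = "CpG")
  pr <- enumerate_cis_pairs(g, sites, window = 20000)
  expect_setequal(pr$site_idx, c(1L, 2L))   # 120001 is 20001 bp away
  # site on another chromosome is never paired
  sites2 <- tibble::tibble(chrom = "chrOther", pos = 100000, context = "CpG")
  expect_equal(nrow(enumerate_cis_pairs(g, sites2, window = 20000)), 0L)
})

test_that("cis pair enumeration matches a brute-force double loop", {
  set.seed(51)
  g <- tiny_cohort$geno
  sites <- tiny_cohort$meth$sites
  pr <- enumerate_cis_pairs(g, sites, window = 3000)
  oracle <- oracle_pairs(g$snps, sites, 3000)
  expect_equal(nrow(pr), nrow(oracle))
  expect_setequal(paste(pr$snp_id, pr$site_idx),
                  paste(oracle$snp_id, oracle$site_idx))
  expect_true(all(pr$distance <= 3000))
})

test_that("fit_pair recovers an exact linear relation and skips degenerate input", {
  dosage <- rep(c(0, 1, 2), each = 5)
  meth <- 0.30 + 0.01 * dosage
  f <- fit_pair(dosage, meth)
  expect_equal(f$slope, 0.01, tolerance = 1e-12)
  expect_equal(f$se, 0, tolerance = 1e-12)

  # constant response: the slope vanishes and no spurious significance arises
  fc <- fit_pair(dosage, rep(0.4, 15))
  expect_lt(abs(fc$slope), 1e-12)
  expect_gt(fc$p, 0.01)

  fs <- fit_pair(rep(1, 15), meth)
  expect_equal(fs$skip, "constant_dosage")
})

test_that("fit_pair matches an explicit normal-equations solve", {
  set.seed(52)
  n <- 50
  dosage <- sample(0:2, n, TRUE)
  covs <- cbind(rnorm(n), runif(n))
  meth <- 0.4 + 0.02 * dosage + 0.1 * covs[, 1] + rnorm(n, 0, 0.05)
  f <- fit_pair(dosage, meth, covs)
  o <- oracle_ols(cbind(1, dosage, covs), meth, j = 2)
  expect_equal(f$slope, o$slope, tolerance = 1e-10)
  expect_equal(f$se, o$se, tolerance = 1e-10)
  expect_equal(f$t, o$t, tolerance = 1e-10)
  expect_equal(f$df, o$df)
  expect_equal(f$p, o$p, tolerance = 1e-10)

  # missing dosages: pairwise complete-case equals the oracle on the subset
  dosage_na <- dosage
  dosage_na[c(3, 7)] <- NA
  fna <- fit_pair(dosage_na, meth, covs)
  ok <- !is.na(dosage_na)
  ona <- oracle_ols(cbind(1, dosage[ok], covs[ok, ]), meth[ok], j = 2)
  expect_equal(fna$slope, ona$slope, tolerance = 1e-10)
  expect_equal(fna$n, sum(ok))
})

test_that("the vectorised scan reproduces per-pair fits exactly", {
  co <- tiny_cohort
  set.seed(53)
  covs <- cbind(age = rnorm(60), pc = rnorm(60))
  scan <- meqtl_scan(co$meth, co$geno, covariates = covs, window = 2000)
  expect_gt(nrow(scan), 0)
  check <- scan[sample.int(nrow(scan), 25), ]
  for (i in seq_len(nrow(check))) {
    y <- co$meth$smoothed[check$site_idx[i], ]
    g <- co$geno$dosage[, check$snp_id[i]]
    f <- fit_pair(g, y, covs)
    expect_equal(check$slope[i], f$slope, tolerance = 1e-10)
    expect_equal(check$t[i], f$t, tolerance = 1e-10)
    expect_equal(check$p[i], f$p, tolerance = 1e-10)
  }
  expect_equal(attr(scan, "n_tests"), nrow(scan))
})

test_that("an empty pair set yields an empty scan with zero tests", {
  co <- tiny_cohort
  empty_pairs <- enumerate_cis_pairs(co$geno, co$meth$sites, window = 2000)[0, ]
  out <- meqtl_scan(co$meth, co$geno, pairs = empty_pairs)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_tests"), 0L)
})

test_that("scan output does not depend on pair enumeration order", {
  co <- tiny_cohort
  pr <- enumerate_cis_pairs(co$geno, co$meth$sites, window = 2000)
  set.seed(54)
  shuffled <- pr[sample.int(nrow(pr)), ]
  s1 <- meqtl_scan(co$meth, co$geno, pairs = pr)
  s2 <- meqtl_scan(co$meth, co$geno, pairs = shuffled)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("an orthogonal covariate changes t only through the df adjustment", {
  set.seed(55)
  n <- 40
  g <- sample(0:2, n, TRUE)
  y <- 0.5 + 0.03 * g + rnorm(n, 0, 0.05)
  z0 <- rnorm(n)
  # orthogonalise z against intercept, dosage and response
  z <- residuals(lm(z0 ~ g + y))
  f1 <- fit_pair(g, y)
  f2 <- fit_pair(g, y, cbind(z))
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$t, f1$t * sqrt(f2$df / f1$df), tolerance = 1e-10)
})

test_that("the FDR-equivalent p cutoff reproduces a hand-run step-up", {
  p <- c(rep(1e-4, 50), rep(0.9, 50))
  expect_equal(fdr_pvalue_cutoff(p, 100, 0.01), 1e-4)
  expect_true(is.na(fdr_pvalue_cutoff(rep(0.9, 100), 100, 0.01)))
  expect_equal(fdr_pvalue_cutoff(0.005, 1, 0.01), 0.005)
  expect_true(is.na(fdr_pvalue_cutoff(numeric(0))))
})

test_that("partial BH adjustment equals p.adjust on a complete vector", {
  set.seed(56)
  p <- runif(300)
  expect_equal(wgbsqtl:::bh_adjust_partial(p, 300), p.adjust(p, "BH"),
               tolerance = 1e-12)
})

test_that("per-SNP summaries recompute widths and slopes from the pair table", {
  pairs <- tibble::tibble(snp_id = c("a", "a", "b"),
                          pos = c(100, 20100, 500),
                          slope = c(0.02, -0.04, 0.01))
  s <- summarize_snp(pairs)
  expect_equal(s$width_bp[s$snp_id == "a"], 20000)
  expect_equal(s$n_sites[s$snp_id == "b"], 1L)
  expect_equal(s$width_bp[s$snp_id == "b"], 0)
  expect_equal(s$mean_abs_slope[s$snp_id == "a"], 0.03)
})

test_that("index-SNP scans label cis/trans by the 250 kb rule", {
  set.seed(57)
  n <- 30
  dos <- matrix(sample(0:2, n, TRUE), n, 1)
  g <- genotypes_from_dosage(dos, pos = 300000)
  vals <- matrix(runif(4 * n), 4, n)
  m <- methylome_from_smoothed(vals, positions = c(50000, 549999, 550000, 550001))
  m$sites$chrom <- "chrSim"
  out <- index_snp_scan(m, g, covariates = NULL, cis_window = 250000)
  lab <- unname(out$cis_flag[match(c(50000, 549999, 550000, 550001), out$pos)])
  expect_equal(lab, c("cis", "cis", "cis", "trans"))
  # a site on another chromosome is trans even when nearby in coordinates
  m2 <- methylome_from_smoothed(vals, positions = c(299000, 301000, 310000, 320000),
                                chrom = "chrOther")
  out2 <- index_snp_scan(m2, g, cis_window = 250000)
  expect_true(all(out2$cis_flag == "trans"))
})

test_that("interaction terms are recovered exactly and match the OLS oracle", {
  n <- 60
  set.seed(58)
  dosage <- sample(0:2, n, TRUE)
  age <- runif(n, 20, 90)
  meth_exact <- 0.3 + 0.001 * dosage * age
  vals <- rbind(meth_exact, runif(n))
  m <- methylome_from_smoothed(vals, positions = c(1000, 2000))
  g <- genotypes_from_dosage(matrix(dosage, n, 1), pos = 1500)
  pairs <- enumerate_cis_pairs(g, m$sites, window = 1000)
  out <- interaction_scan(m, g, pairs, modifier = age)
  r1 <- out[out$site_idx == 1, ]
  expect_equal(r1$interaction, 0.001, tolerance = 1e-9)

  # random pair against the explicit design-matrix oracle
  r2 <- out[out$site_idx == 2, ]
  X <- cbind(1, dosage, age, dosage * age)
  o <- oracle_ols(X, vals[2, ], j = 4)
  expect_equal(r2$interaction, o$slope, tolerance = 1e-10)
  expect_equal(r2$t, o$t, tolerance = 1e-10)
  expect_equal(r2$p, o$p, tolerance = 1e-10)

  expect_error(interaction_scan(m, g, pairs, modifier = rep(1, n)),
               "constant")
})
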