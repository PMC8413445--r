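make_cov_file <- function(path, tab) {
  readr::write_tsv(tab, path, col_names = FALSE, progress = FALSE)
  path
}

test_that("identical per-sample count files load into matched matrices", {
  tab <- tibble::tibble(chrom = "chr1", pos = c(10, 20, 30, 40, 50),
                        end = c(10, 20, 30, 40, 50), pct = 50,
                        n_meth = 2L, n_unmeth = 2L, context = "CpG")
  d <- withr::local_tempdir()
  p1 <- make_cov_file(file.path(d, "a.cov"), tab)
  p2 <- make_cov_file(file.path(d, "b.cov"), tab)
  m <- read_methylome(c(p1, p2))
  expect_equal(dim(m), c(5L, 2L))
  expect_true(all(m$methylated == 2L))
  expect_true(all(m$coverage == 4L))
  expect_equal(m$samples, c("a", "b"))
})

test_that("count files violating methylated <= coverage are rejected by name and line", {
  d <- withr::local_tempdir()
  # methylated 7 of coverage 5 encodes as a negative unmethylated count
  bad <- tibble::tibble(chrom = "chr1", pos = c(10, 20), end = c(10, 20),
                        pct = 100, n_meth = c(3L, 7L), n_unmeth = c(1L, -2L))
  p <- make_cov_file(file.path(d, "bad.cov"), bad)
  expect_error(read_methylome(p), "bad\\.cov line 2")
})

test_that("duplicate sites within a count file are rejected", {
  d <- withr::local_tempdir()
  dup <- tibble::tibble(chrom = "chr1", pos = c(10, 10), end = c(10, 10),
                        pct = 50, n_meth = 1L, n_unmeth = 1L)
  p <- make_cov_file(file.path(d, "dup.cov"), dup)
  expect_error(read_methylome(p), "duplicate")
})

test_that("a methylome survives a write/read round trip", {
  m <- tiny_cohort$meth
  d <- withr::local_tempdir()
  write_bismark_cov(m, d)
  back <- read_methylome(file.path(d, paste0(m$samples, ".cov")),
                         sample_ids = m$samples)
  # simulated coverage is zero-truncated, so every site is written
  expect_equal(back$sites$pos, m$sites$pos)
  expect_equal(back$sites$context, m$sites$context)
  expect_equal(unname(back$methylated), unname(m$methylated))
  expect_equal(unname(back$coverage), unname(m$coverage))
})

test_that("the CpG coverage filter applies the mean rule and is idempotent", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(10, 20, 30),
                          context = "CpG")
  cov <- rbind(c(3L, 3L, 3L), c(0L, 0L, 0L), c(9L, 0L, 0L))
  meth <- matrix(0L, 3, 3)
  m <- methylome(sites, meth, cov, c("s1", "s2", "s3"))
  f <- filter_cpg(m, min_cov = 3)
  expect_equal(f$sites$pos, c(10, 30))  # mean 3 kept, mean 0 dropped, mean 3 kept
  expect_equal(filter_cpg(f, min_cov = 3)$sites$pos, f$sites$pos)
  # per-sample "all" rule is stricter
  expect_equal(filter_cpg(m, min_cov = 3, rule = "all")$sites$pos, 10)
})

test_that("random CpG filtering matches brute-force per-site recomputation", {
  set.seed(21)
  ns <- 1000
  sites <- tibble::tibble(chrom = "chr1", pos = seq_len(ns), context = "CpG")
  cov <- matrix(rpois(ns * 8, 3), ns, 8)
  meth <- matrix(0L, ns, 8)
  m <- methylome(sites, meth, cov, sprintf("s%d", 1:8))
  f <- filter_cpg(m, min_cov = 3)
  keep <- vapply(seq_len(ns), function(i) mean(cov[i, ]) >= 3, logical(1))
  expect_equal(f$sites$pos, sites$pos[keep])
})

test_that("the CpH filter requires joint coverage and non-zero methylation in half the samples", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(10, 20),
                          context = "CpH")
  # site 1: methylated in 2 of 4 samples with coverage 5 -> retained
  # site 2: methylated in 1 of 4 -> dropped
  cov <- rbind(c(5L, 5L, 5L, 5L), c(5L, 5L, 5L, 5L))
  meth <- rbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L))
  m <- methylome(sites, meth, cov, sprintf("s%d", 1:4))
  f <- filter_cph(m)
  expect_equal(f$sites$pos, 10)
  expect_equal(filter_cph(f)$sites$pos, 10)
})

test_that("random CpH filtering matches brute-force recomputation", {
  set.seed(22)
  ns <- 500
  sites <- tibble::tibble(chrom = "chr1", pos = seq_len(ns), context = "CpH")
  cov <- matrix(rpois(ns * 6, 5), ns, 6)
  meth <- matrix(rbinom(ns * 6, as.vector(cov), 0.2), ns, 6)
  m <- methylome(sites, meth, cov, sprintf("s%d", 1:6))
  f <- filter_cph(m, min_cov = 4, min_nonzero_frac = 0.5)
  keep <- vapply(seq_len(ns), function(i) {
    mean(cov[i, ] >= 4 & meth[i, ] > 0) >= 0.5
  }, logical(1))
  expect_equal(f$sites$pos, sites$pos[keep])
})

test_that("blacklist exclusion honours the 0-based half-open convention", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(100, 101), context = "CpG")
  bl <- tibble::tibble(chrom = "chr1", start = 99, end = 100)
  out <- exclude_blacklist(sites, bl)
  expect_equal(out$pos, 101)   # pos 100 covered by [99,100); pos 101 not
  expect_equal(exclude_blacklist(sites, bl[0, ]), sites)  # empty = identity
})

test_that("blacklist exclusion matches a brute-force double loop", {
  set.seed(23)
  sites <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 2000, TRUE),
                          pos = sample.int(5000, 2000, TRUE),
                          context = "CpG") |>
    dplyr::distinct(chrom, pos, .keep_all = TRUE) |>
    dplyr::arrange(chrom, pos)
  st <- sample.int(5000, 80, TRUE)
  bl <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 80, TRUE),
                       start = st, end = st + sample.int(100, 80, TRUE))
  out <- exclude_blacklist(sites, bl)
  hit <- vapply(seq_len(nrow(sites)), function(i) {
    any(bl$chrom == sites$chrom[i] &
          bl$start < sites$pos[i] & sites$pos[i] <= bl$end)
  }, logical(1))
  expect_equal(out$pos, sites$pos[!hit])
})

test_that("BED parsing converts coordinates and flags malformed lines", {
  d <- withr::local_tempdir()
  p <- file.path(d, "ok.bed")
  writeLines(c("chr1\t99\t100", "chr2\t0\t10"), p)
  b <- read_bed(p)
  expect_equal(b$start1, c(100, 1))
  expect_equal(b$end1, c(100, 10))
  p2 <- file.path(d, "bad.bed")
  writeLines(c("chr1\t99\t100", "chr1\t5"), p2)
  expect_error(read_bed(p2), "line 2")
  p3 <- file.path(d, "inverted.bed")
  writeLines("chr1\t10\t10", p3)
  expect_error(read_bed(p3), "line 1")
})

test_that("VCF genotypes round-trip and QC filters drop failing SNPs", {
  d <- withr::local_tempdir()
  # round trip of a simulated set (all SNPs pass QC by construction)
  g <- tiny_cohort$geno
  p <- file.path(d, "sim.vcf")
  write_vcf(g, p)
  back <- read_genotypes(p)
  expect_equal(unname(back$dosage), unname(g$dosage[, back$snps$snp_id]))

  # constructed failures: low MAF, high missingness, extreme HWE departure
  n <- 100
  dos <- cbind(
    lowmaf = c(rep(1L, 8), rep(0L, 92)),                # alt freq 0.04
    missing = c(rep(NA_integer_, 15), rep(1L, 45), rep(0L, 40)),
    hwe = c(rep(0L, 50), rep(2L, 50)),                  # 50/0/50: no hets
    good = rep(c(0L, 1L, 1L, 2L), 25)
  )
  rownames(dos) <- sprintf("P%03d", seq_len(n))
  gg <- genotypes_from_dosage(dos, pos = c(100, 200, 300, 400))
  p2 <- file.path(d, "qc.vcf")
  write_vcf(gg, p2)
  kept <- read_genotypes(p2)
  expect_equal(kept$snps$snp_id, "s004")
})

test_that("the Hardy-Weinberg chi-square matches a hand computation", {
  # 50/0/50: p = 0.5, expected (25, 50, 25), chi-square = 25+50+25 = 100
  expect_equal(hwe_test(50, 0, 50), pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hwe_test(50, 0, 50), 1e-6)
  expect_equal(hwe_test(25, 50, 25), 1)   # exact HWE proportions
})
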