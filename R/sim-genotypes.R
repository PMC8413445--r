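#' Simulate genotype dosages under Hardy-Weinberg with block LD
#'
#' Draws biallelic SNPs at positions uniform over the chromosome (then
#' sorted), each with a minor allele frequency sampled from
#' `config$maf_range`. Haplotypes are generated with a Gaussian-copula AR(1)
#' latent process inside LD blocks of `ld_block_size` SNPs, so adjacent SNPs
#' within a block are correlated (tunable via `ld_rho`) while marginal
#' genotype frequencies follow Hardy-Weinberg proportions exactly. The two
#' haplotypes of a donor are independent, and dosage is their sum.
#'
#' @param config A [sim_config()].
#' @return A `genotype_set`: list with `snps` (tibble: snp_id, chrom, pos,
#'   maf, missingness, hwe_p), `dosage` (samples x SNPs integer matrix in
#'   {0,1,2}) and `samples` (character ids).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 2) rlang::abort("need at least 2 samples to simulate genotypes")
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_snps

  pos <- sort(sample.int(config$chrom_length, m, replace = FALSE))
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  blocks <- split(seq_len(m), ceiling(seq_len(m) / config$ld_block_size))
  hap <- function() {
    h <- matrix(0L, n, m)
    for (idx in blocks) {
      k <- length(idx)
      z <- matrix(stats::rnorm(n * k), n, k)
      if (k > 1) {
        for (j in 2:k) {
          z[, j] <- config$ld_rho * z[, j - 1] +
            sqrt(1 - config$ld_rho^2) * z[, j]
        }
      }
      # threshold the latent normal at the allele-frequency quantile
      h[, idx] <- sweep(z, 2, stats::qnorm(maf[idx]), `<`) + 0L
    }
    h
  }
  dosage <- hap() + hap()
  storage.mode(dosage) <- "integer"

  samples <- sprintf("S%03d", seq_len(n))
  rownames(dosage) <- samples
  snp_id <- sprintf("snp_%05d", seq_len(m))
  colnames(dosage) <- snp_id

  new_genotype_set(
    snps = tibble::tibble(
      snp_id = snp_id, chrom = "chrSim", pos = pos,
      maf = maf, missingness = 0, hwe_p = NA_real_
    ),
    dosage = dosage, samples = samples
  )
}

new_genotype_set <- function(snps, dosage, samples) {
  stopifnot(nrow(dosage) == length(samples), ncol(dosage) == nrow(snps))
  structure(list(snps = snps, dosage = dosage, samples = samples),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set> %d SNPs x %d samples\n",
              nrow(x$snps), length(x$samples)))
  print(utils::head(x$snps, 5))
  invisible(x)
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' One-degree-of-freedom goodness-of-fit of observed hom-ref / het / hom-alt
#' counts against p^2, 2pq, q^2 at the estimated allele frequency.
#'
#' @param n0,n1,n2 Vectors of genotype counts (ref hom, het, alt hom).
#' @return Two-sided p-values.
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n0 + n1) / (2 * n)
  e <- cbind(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
  o <- cbind(n0, n1, n2)
  chi <- rowSums((o - e)^2 / pmax(e, .Machine$double.eps))
  out <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  out[p %in% c(0, 1)] <- 1  # monomorphic: nothing to test
  out
}
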