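#' Simulate expression with controlled methylation mediation, and GWAS
#' summary statistics under a stratified heritability model
#'
#' For each requested mediation proportion, a (SNP, CpG, gene) triplet is
#' built from the recorded effect pairs: expression is
#' `gamma * dosage + alpha * methylation + noise`, with gamma and alpha set
#' so that the true proportion of the genotype effect retained after
#' adjusting for methylation equals `1 - proportion`. GWAS z-scores are
#' drawn with per-SNP variance `1 + N * sum_c tau_c * l_{j,c}` (the
#' stratified LD-score model), so annotation enrichment is recoverable
#' downstream.
#'
#' @param genotypes A `genotype_set`.
#' @param sim Output of [simulate_methylome()] (its truth table must contain
#'   effect pairs when mediation triplets are requested).
#' @param config The [sim_config()].
#' @param mediation_props True mediation proportions, one triplet each
#'   (default none).
#' @param annotations Logical SNPs x annotations matrix for the GWAS model
#'   (default a single all-SNP column).
#' @param tau Per-annotation coefficients of the stratified model (default
#'   0).
#' @param n_gwas GWAS sample size (default 50000).
#' @param ld_window LD-score window passed to [ld_scores()].
#' @return List: `expression` (features x samples), `features` tibble
#'   (feature_id, level), `gwas` tibble (snp_id, chrom, pos, n, z, chisq),
#'   `truth` (the input truth table with a `mediation` tibble added),
#'   `ld` (the [ld_scores()] table used).
#' @export
simulate_expression_and_gwas <- function(genotypes, sim, config,
                                         mediation_props = numeric(0),
                                         annotations = NULL, tau = NULL,
                                         n_gwas = 5e4, ld_window = 1e6) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  truth <- sim$truth
  n <- config$n_samples

  expression <- NULL
  features <- tibble::tibble(feature_id = character(0), level = character(0))
  med_truth <- NULL
  if (length(mediation_props)) {
    pe <- dplyr::filter(truth$pair_effects, .data$context == "CpG")
    if (!nrow(pe)) {
      rlang::abort("mediation triplets requested but the truth table has no meQTL effects")
    }
    # one well-separated effect pair per triplet: pick the mid-window site of
    # distinct SNPs
    snps <- unique(pe$snp_id)
    if (length(snps) < length(mediation_props)) {
      snps <- rep(snps, length.out = length(mediation_props))
    }
    rows <- vapply(seq_along(mediation_props), function(i) {
      cand <- which(pe$snp_id == snps[i])
      cand[ceiling(length(cand) / 2)]
    }, integer(1))
    levels <- rep(c("gene", "exon", "junction"), length.out = length(rows))
    expression <- matrix(0, length(rows), n)
    med_truth <- tibble::tibble(
      snp_id = pe$snp_id[rows], site_idx = pe$site_idx[rows],
      feature_id = sprintf("feat_%03d", seq_along(rows)),
      level = levels, true_prop_mediated = mediation_props
    )
    for (i in seq_along(rows)) {
      g <- genotypes$dosage[, med_truth$snp_id[i]]
      meth <- sim$fractions[med_truth$site_idx[i], ]
      b <- pe$delta[rows[i]]             # methylation change per allele
      total <- 1                          # total genotype effect on expression
      gamma <- (1 - mediation_props[i]) * total
      alpha <- mediation_props[i] * total / b
      expression[i, ] <- gamma * g + alpha * meth + stats::rnorm(n, 0, 0.5)
    }
    rownames(expression) <- med_truth$feature_id
    colnames(expression) <- genotypes$samples
    features <- med_truth[, c("feature_id", "level")]
  }

  if (is.null(annotations)) {
    annotations <- matrix(TRUE, config$n_snps, 1,
                          dimnames = list(NULL, "full_genome"))
  }
  if (is.null(tau)) tau <- rep(0, ncol(annotations))
  ld <- ld_scores(genotypes, annotations, window = ld_window)
  lmat <- as.matrix(ld[, paste0("l_", colnames(annotations)), drop = FALSE])
  ev <- pmax(1 + n_gwas * as.vector(lmat %*% tau), 1e-8)
  z <- stats::rnorm(config$n_snps, 0, sqrt(ev))
  gwas <- tibble::tibble(
    snp_id = genotypes$snps$snp_id, chrom = genotypes$snps$chrom,
    pos = genotypes$snps$pos, n = n_gwas, z = z, chisq = z^2
  )

  truth$mediation <- med_truth
  list(expression = expression, features = features, gwas = gwas,
       truth = truth, ld = ld)
}

#' Write sample covariates as TSV
#'
#' @param covariates Covariate tibble from [simulate_methylome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_tsv(covariates, path, progress = FALSE)
  invisible(path)
}

#' Write GWAS summary statistics as TSV (SNP, chrom, pos, N, Z)
#'
#' @param gwas GWAS tibble from [simulate_expression_and_gwas()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gwas <- function(gwas, path) {
  readr::write_tsv(
    dplyr::select(gwas, SNP = "snp_id", chrom = "chrom", pos = "pos",
                  N = "n", Z = "z"),
    path, progress = FALSE)
  invisible(path)
}
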