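#' Annotation-partitioned LD scores
#'
#' For SNP j and annotation c, l_{j,c} is the sum over SNPs k within
#' `window` bp (including j itself) and inside c of the adjusted squared
#' correlation r2_adj = r2 - (1 - r2)/(n - 2).
#'
#' @param genotypes A `genotype_set` (positions sorted).
#' @param annotations Logical matrix, SNPs x annotations (a column of all
#'   TRUE is the full-genome baseline).
#' @param window LD window in bp (default 1 Mb; a warning is issued when it
#'   exceeds the chromosome and the full chromosome is used).
#' @return An `ld_score_table`: tibble with snp_id, pos and one `l_<name>`
#'   column per annotation; attribute `annotations` keeps the matrix.
#' @export
ld_scores <- function(genotypes, annotations, window = 1e6) {
  d <- genotypes$dosage
  m <- ncol(d)
  n <- nrow(d)
  ann <- as.matrix(annotations)
  stopifnot(nrow(ann) == m)
  if (is.null(colnames(ann))) colnames(ann) <- paste0("A", seq_len(ncol(ann)))
  pos <- genotypes$snps$pos
  if (window >= max(pos) - min(pos)) {
    rlang::warn("LD window spans the whole chromosome; using all SNP pairs")
  }
  ds <- scale(d)                 # correlation via standardized crossproduct
  L <- matrix(0, m, ncol(ann))
  for (j in seq_len(m)) {
    lo <- findInterval(pos[j] - window, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos[j] + window, pos)
    k <- lo:hi
    r <- crossprod(ds[, k, drop = FALSE], ds[, j]) / (n - 1)
    r2 <- pmin(r^2, 1)
    r2a <- r2 - (1 - r2) / (n - 2)
    L[j, ] <- crossprod(ann[k, , drop = FALSE], r2a)
  }
  out <- tibble::tibble(snp_id = genotypes$snps$snp_id, pos = pos)
  for (c in seq_len(ncol(ann))) out[[paste0("l_", colnames(ann)[c])]] <- L[, c]
  structure(out, annotations = ann, class = c("ld_score_table", class(out)))
}

#' Stratified LD-score regression for partitioned heritability
#'
#' Regresses per-SNP GWAS chi-square statistics on N-scaled partitioned LD
#' scores (weighted least squares with the standard 1/(2 l_total^2)
#' heteroskedasticity weights, plus an intercept), then converts the
#' coefficients tau_c into per-annotation heritability shares and
#' enrichment = share / SNP proportion. Standard errors come from a block
#' jackknife over contiguous SNP blocks.
#'
#' @param chisq Per-SNP chi-square statistics (z^2).
#' @param ld A [ld_scores()] table (the annotation matrix rides along as an
#'   attribute).
#' @param n_gwas GWAS sample size.
#' @param n_blocks Jackknife blocks (default 20).
#' @return A `partitioned_h2` object: tibble per annotation with tau,
#'   tau_se, h2_share, share_se, prop_snps, enrichment, enrichment_se, p
#'   (two-sided on enrichment - 1); attributes `intercept` and `h2_total`.
#' @export
stratified_regression <- function(chisq, ld, n_gwas, n_blocks = 20) {
  ann <- attr(ld, "annotations")
  lmat <- as.matrix(ld[, paste0("l_", colnames(ann)), drop = FALSE])
  m <- length(chisq)
  stopifnot(nrow(lmat) == m)
  X <- cbind(intercept = 1, n_gwas * lmat)
  if (qr(X)$rank < ncol(X)) {
    rlang::abort(paste("collinear annotations:", paste(colnames(ann), collapse = ", ")))
  }
  full_cols <- which(colSums(!ann) == 0)
  w <- if (length(full_cols)) {
    1 / (2 * pmax(lmat[, full_cols[1]], 1)^2)  # standard LDSC-style weights
  } else {
    rep(1, m)                                  # no genome-wide column: OLS
  }

  fit_wls <- function(rows) {
    Xw <- X[rows, , drop = FALSE] * sqrt(w[rows])
    yw <- chisq[rows] * sqrt(w[rows])
    stats::lm.fit(Xw, yw)$coefficients
  }
  full <- fit_wls(seq_len(m))

  stat_fun <- function(coefs) {
    tau <- coefs[-1]
    per_snp <- as.vector(ann %*% tau)      # expected h2 contribution per SNP
    h2_tot <- sum(per_snp)
    share <- as.vector(crossprod(ann, per_snp)) / h2_tot
    prop <- colMeans(ann)
    unname(c(tau, share, share / prop))
  }
  full_stat <- stat_fun(full)

  blocks <- split(seq_len(m), cut(seq_len(m), n_blocks, labels = FALSE))
  jk <- vapply(blocks, function(b) stat_fun(fit_wls(setdiff(seq_len(m), b))),
               numeric(length(full_stat)))
  nb <- length(blocks)
  jk_mean <- rowMeans(jk)
  jk_se <- sqrt((nb - 1) / nb * rowSums((jk - jk_mean)^2))

  k <- ncol(ann)
  tau <- full_stat[1:k]
  share <- full_stat[k + (1:k)]
  enr <- full_stat[2 * k + (1:k)]
  tau_se <- jk_se[1:k]
  share_se <- jk_se[k + (1:k)]
  enr_se <- jk_se[2 * k + (1:k)]
  z <- (enr - 1) / enr_se
  out <- tibble::tibble(
    annotation = colnames(ann), tau = tau, tau_se = tau_se,
    h2_share = share, share_se = share_se, prop_snps = colMeans(ann),
    enrichment = enr, enrichment_se = enr_se,
    p = 2 * stats::pnorm(-abs(z))
  )
  structure(out, intercept = unname(full[1]),
            h2_total = sum(as.vector(ann %*% tau)),
            class = c("partitioned_h2", class(out)))
}

#' @method glance partitioned_h2
#' @export
glance.partitioned_h2 <- function(x, ...) {
  tibble::tibble(intercept = attr(x, "intercept"),
                 h2_total = attr(x, "h2_total"),
                 n_annotations = nrow(x))
}
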