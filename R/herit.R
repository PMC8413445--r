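#' Genetic relationship matrix from standardized dosages
#'
#' A = Z Z' / m with Z the column-standardized dosage matrix (each SNP
#' centred at 2p and scaled by sqrt(2p(1-p))). Monomorphic SNPs are skipped
#' with their count recorded.
#'
#' @param dosages Samples x SNPs matrix in \{0,1,2\} (the window SNPs
#'   around a site, or all SNPs).
#' @return A `grm` object: `A` (samples x samples), `n_snps` used,
#'   `n_monomorphic` skipped.
#' @export
compute_grm <- function(dosages) {
  d <- as.matrix(dosages)
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) rlang::abort("all SNPs are monomorphic")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(sweep(d, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), `/`)
  Z[is.na(Z)] <- 0
  A <- tcrossprod(Z) / ncol(Z)
  rownames(A) <- colnames(A) <- rownames(d)
  structure(list(A = A, n_snps = ncol(Z), n_monomorphic = sum(!poly)),
            class = "grm")
}

#' Greedy relatedness pruning
#'
#' Repeatedly drops, among samples involved in off-diagonal relatedness at
#' or above `threshold`, the sample with the most offending partners (ties
#' broken by id order) until no offending pair remains.
#'
#' @param grm A `grm` (or a plain symmetric matrix).
#' @param threshold Relatedness cutoff (default 0.025).
#' @return Character/integer vector of retained sample ids (names when the
#'   matrix has them, row indices otherwise).
#' @export
prune_related <- function(grm, threshold = 0.025) {
  A <- if (inherits(grm, "grm")) grm$A else as.matrix(grm)
  ids <- rownames(A) %||% as.character(seq_len(nrow(A)))
  keep <- rep(TRUE, nrow(A))
  off <- A
  diag(off) <- 0
  repeat {
    bad <- (abs(off) >= threshold) & outer(keep, keep, `&`)
    counts <- rowSums(bad)
    if (all(counts == 0)) break
    worst <- which(counts == max(counts))[1]
    keep[worst] <- FALSE
  }
  ids[keep]
}

#' Single-component REML heritability of a trait
#'
#' Mixed model y = X b + g + e with g ~ N(0, sigma_g^2 A). Covariates are
#' projected out (restricted likelihood); the projected GRM is
#' eigendecomposed once and the restricted likelihood, with the total
#' variance profiled out analytically, is maximized over h^2 = sigma_g^2 /
#' (sigma_g^2 + sigma_e^2) on [0, 1] by 1-D optimization. The likelihood-
#' ratio test against h^2 = 0 uses the boundary-corrected 50:50 chi-square
#' mixture.
#'
#' @param y Per-sample trait (e.g. smoothed methylation at one site).
#' @param grm A `grm` on the same samples.
#' @param covariates Optional numeric matrix (samples x k); an intercept is
#'   always included.
#' @return One-row tibble: h2, se, sigma2_total, loglik, lrt, p, boundary
#'   (estimate at 0 or 1), non_identifiable (GRM close to identity).
#' @export
reml_h2 <- function(y, grm, covariates = NULL) {
  A <- if (inherits(grm, "grm")) grm$A else as.matrix(grm)
  n <- length(y)
  stopifnot(nrow(A) == n)
  X <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  qx <- qr(X)
  Qc <- qr.Q(qx, complete = TRUE)[, -(seq_len(qx$rank)), drop = FALSE]
  K <- crossprod(Qc, A %*% Qc)
  eig <- eigen(K, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  yt <- crossprod(eig$vectors, crossprod(Qc, y))[, 1]
  nr <- length(yt)

  non_identifiable <- stats::sd(lam) < 1e-6

  nll <- function(h2) {
    v <- h2 * lam + (1 - h2)
    v <- pmax(v, 1e-12)
    s2 <- mean(yt^2 / v)
    0.5 * (sum(log(v)) + nr * log(max(s2, 1e-300)) + nr)
  }
  opt <- stats::optimize(nll, c(0, 1), tol = 1e-8)
  # ensure boundary values are not better than the interior optimum
  cand <- c(opt$minimum, 0, 1)
  vals <- c(opt$objective, nll(0), nll(1))
  h2 <- cand[which.min(vals)]
  ll <- -min(vals)
  lrt <- max(0, 2 * (ll - (-nll(0))))
  p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (lrt == 0) p <- 1

  # SE from the curvature of the profile restricted likelihood
  eps <- 1e-4
  h2e <- min(max(h2, eps), 1 - eps)
  hess <- (nll(h2e + eps) - 2 * nll(h2e) + nll(h2e - eps)) / eps^2
  se <- if (is.finite(hess) && hess > 0) sqrt(1 / hess) else NA_real_

  v <- pmax(h2 * lam + (1 - h2), 1e-12)
  tibble::tibble(
    h2 = h2, se = se, sigma2_total = mean(yt^2 / v), loglik = ll,
    lrt = lrt, p = p, boundary = h2 %in% c(0, 1),
    non_identifiable = non_identifiable
  )
}

#' Cis-window SNP heritability for each of several sites
#'
#' For each site, builds the GRM from SNPs within `window` bp and runs
#' [reml_h2()] on its smoothed methylation.
#'
#' @param m Smoothed [methylome()] restricted to the pruned samples.
#' @param genotypes `genotype_set` on the same samples.
#' @param site_idx Sites to analyse (default all).
#' @param window GRM window in bp around the site (40 kb, 200 kb and 1 Mb
#'   are the conventional choices; default 40 kb).
#' @param covariates Optional matrix as in [reml_h2()].
#' @return Tibble: site_idx, pos, n_snps, and the [reml_h2()] columns.
#' @export
site_h2_scan <- function(m, genotypes, site_idx = seq_len(nrow(m$sites)),
                         window = 40000, covariates = NULL) {
  purrr::map_dfr(site_idx, function(i) {
    sel <- genotypes$snps$chrom == m$sites$chrom[i] &
      abs(genotypes$snps$pos - m$sites$pos[i]) <= window
    if (!any(sel)) {
      return(tibble::tibble(site_idx = i, pos = m$sites$pos[i], n_snps = 0L))
    }
    g <- compute_grm(genotypes$dosage[, sel, drop = FALSE])
    dplyr::bind_cols(
      tibble::tibble(site_idx = i, pos = m$sites$pos[i], n_snps = g$n_snps),
      reml_h2(m$smoothed[i, ], g, covariates)
    )
  })
}
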