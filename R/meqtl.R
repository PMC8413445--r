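#' Enumerate cis SNP-site pairs within a bp window
#'
#' Yields every (SNP, site) pair on the same chromosome with
#' `|pos_snp - pos_site| <= window` (inclusive), each exactly once, via a
#' two-pointer sweep over the position-sorted inputs.
#'
#' @param genotypes A `genotype_set`.
#' @param sites Site tibble (`chrom`, `pos`, `context`), sorted by position.
#' @param window Maximum SNP-to-site distance in bp (default 20 kb).
#' @return Tibble: `snp_id`, `snp_pos`, `site_idx` (row in `sites`),
#'   `site_pos`, `chrom`, `context`, `distance`.
#' @export
enumerate_cis_pairs <- function(genotypes, sites, window = 20000) {
  stopifnot(inherits(genotypes, "genotype_set"))
  sites <- tibble::as_tibble(sites)
  out <- vector("list", 0L)
  for (ch in unique(genotypes$snps$chrom)) {
    sn <- genotypes$snps[genotypes$snps$chrom == ch, ]
    on_ch <- which(sites$chrom == ch)
    if (!nrow(sn) || !length(on_ch)) next
    sp <- sites$pos[on_ch]
    lo <- findInterval(sn$pos - window, sp, left.open = TRUE) + 1L
    hi <- findInterval(sn$pos + window, sp)
    n_each <- pmax(0L, hi - lo + 1L)
    keep <- n_each > 0L
    if (!any(keep)) next
    site_rows <- unlist(lapply(which(keep), function(i) lo[i]:hi[i]))
    out[[length(out) + 1L]] <- tibble::tibble(
      snp_id = rep(sn$snp_id[keep], n_each[keep]),
      snp_pos = rep(sn$pos[keep], n_each[keep]),
      site_idx = on_ch[site_rows],
      site_pos = sp[site_rows],
      chrom = ch,
      context = sites$context[on_ch[site_rows]]
    )
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(snp_id = character(0), snp_pos = numeric(0),
                   site_idx = integer(0), site_pos = numeric(0),
                   chrom = character(0), context = character(0))
  dplyr::mutate(res, distance = abs(.data$snp_pos - .data$site_pos))
}

#' OLS association of methylation with genotype dosage
#'
#' Ordinary least squares of `meth` on `[intercept, dosage, covariates]`,
#' with pairwise complete-case deletion of missing dosages. The reported t,
#' p and residual df refer to the dosage coefficient.
#'
#' @param dosage Per-sample alternate-allele counts (may contain NA).
#' @param meth Per-sample methylation levels.
#' @param covariates Optional numeric matrix (samples x k), no intercept.
#' @return One-row tibble: slope, se, t, df, p, n, skip (NA or a reason
#'   code: "constant_dosage", "insufficient_df").
#' @export
fit_pair <- function(dosage, meth, covariates = NULL) {
  ok <- !is.na(dosage) & !is.na(meth)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  g <- dosage[ok]
  y <- meth[ok]
  X <- cbind(`(Intercept)` = 1, dosage = g,
             if (!is.null(covariates)) as.matrix(covariates)[ok, , drop = FALSE])
  skip <- NA_character_
  if (length(unique(g)) < 2) {
    skip <- "constant_dosage"
  } else if (length(y) < ncol(X) + 1) {
    skip <- "insufficient_df"
  }
  if (!is.na(skip)) {
    return(tibble::tibble(slope = NA_real_, se = NA_real_, t = NA_real_,
                          df = NA_integer_, p = NA_real_, n = length(y),
                          skip = skip))
  }
  fit <- stats::lm.fit(X, y)
  df <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)
  slope <- fit$coefficients[["dosage"]]
  se <- sqrt(max(rss, 0) / max(df, 1) * xtx_inv[2, 2])
  t <- if (se > 0) slope / se else 0
  p <- 2 * stats::pt(-abs(t), df)
  tibble::tibble(slope = slope, se = se, t = t, df = df,
                 p = max(p, .Machine$double.xmin), n = length(y),
                 skip = NA_character_)
}

#' Windowed cis-meQTL scan
#'
#' Applies the covariate-adjusted linear model of [fit_pair()] to every
#' enumerated pair (vectorised per SNP through the
#' Frisch-Waugh residualisation, which is exact for OLS), retains pairs with
#' `p <= p_keep`, and BH-adjusts against the full number of tests performed.
#'
#' @param m A smoothed [methylome()].
#' @param genotypes A `genotype_set` on the same samples.
#' @param covariates Numeric matrix (samples x k) of adjustment covariates,
#'   e.g. methylation PCs from [meth_pca()]; may be NULL.
#' @param pairs Pair tibble from [enumerate_cis_pairs()]; computed with
#'   `window` when NULL.
#' @param window Passed to [enumerate_cis_pairs()] when `pairs` is NULL.
#' @param p_keep Retain pairs with p at or below this value (default 1).
#' @return Tibble of `meqtl_pair` rows: snp_id, chrom, pos (site), context,
#'   distance, slope, se, t, df, p, q; sorted by (chrom, pos, snp_id).
#'   Attributes: `n_tests` (tests performed), `n_skipped`.
#' @export
meqtl_scan <- function(m, genotypes, covariates = NULL, pairs = NULL,
                       window = 20000, p_keep = 1) {
  stopifnot(inherits(m, "methylome"), inherits(genotypes, "genotype_set"))
  if (is.null(m$smoothed)) rlang::abort("scan uses smoothed values; run smooth_methylome()")
  if (!identical(m$samples, genotypes$samples)) {
    rlang::abort("methylome and genotypes must share the same samples in order")
  }
  if (is.null(pairs)) pairs <- enumerate_cis_pairs(genotypes, m$sites, window)
  empty <- tibble::tibble(
    snp_id = character(0), chrom = character(0), pos = numeric(0),
    context = character(0), distance = numeric(0), slope = numeric(0),
    se = numeric(0), t = numeric(0), df = integer(0), p = numeric(0),
    q = numeric(0))
  if (!nrow(pairs)) {
    attr(empty, "n_tests") <- 0L
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }

  n <- length(m$samples)
  X <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  Q <- qr.Q(qr(X))
  k <- ncol(Q)
  df <- n - k - 1L

  Y <- m$smoothed
  Yr <- Y - (Y %*% Q) %*% t(Q)
  yty <- rowSums(Yr^2)

  by_snp <- split(seq_len(nrow(pairs)), pairs$snp_id)
  res <- vector("list", length(by_snp))
  n_skipped <- 0L
  for (s in seq_along(by_snp)) {
    rows <- by_snp[[s]]
    sid <- pairs$snp_id[rows[1]]
    g <- genotypes$dosage[, sid]
    if (anyNA(g)) {
      # pairwise complete-case: refit the projection on observed samples
      fits <- lapply(rows, function(r) {
        fit_pair(g, Y[pairs$site_idx[r], ], covariates)
      })
      tab <- dplyr::bind_rows(fits)
      n_skipped <- n_skipped + sum(!is.na(tab$skip))
      res[[s]] <- dplyr::mutate(tab[, c("slope", "se", "t", "df", "p")],
                                row = rows)
      next
    }
    gr <- g - Q %*% crossprod(Q, g)
    gg <- sum(gr^2)
    if (gg < .Machine$double.eps * n || length(unique(g)) < 2) {
      n_skipped <- n_skipped + length(rows)
      res[[s]] <- tibble::tibble(slope = NA_real_, se = NA_real_, t = NA_real_,
                                 df = NA_integer_, p = NA_real_, row = rows)
      next
    }
    si <- pairs$site_idx[rows]
    gy <- as.vector(Yr[si, , drop = FALSE] %*% gr)
    slope <- gy / gg
    rss <- pmax(yty[si] - slope^2 * gg, 0)
    se <- sqrt(rss / df / gg)
    t <- ifelse(se > 0, slope / se, 0)
    p <- pmax(2 * stats::pt(-abs(t), df), .Machine$double.xmin)
    res[[s]] <- tibble::tibble(slope = slope, se = se, t = t,
                               df = as.integer(df), p = p, row = rows)
  }
  tab <- dplyr::bind_rows(res)
  n_tests <- sum(!is.na(tab$p))
  tab <- tab[!is.na(tab$p) & tab$p <= p_keep, ]

  out <- tibble::tibble(
    snp_id = pairs$snp_id[tab$row],
    chrom = pairs$chrom[tab$row],
    pos = pairs$site_pos[tab$row],
    site_idx = pairs$site_idx[tab$row],
    context = pairs$context[tab$row],
    distance = pairs$distance[tab$row],
    slope = tab$slope, se = tab$se, t = tab$t, df = tab$df, p = tab$p,
    q = bh_adjust_partial(tab$p, n_tests)
  )
  out <- dplyr::arrange(out, .data$chrom, .data$pos, .data$snp_id)
  attr(out, "n_tests") <- n_tests
  attr(out, "n_skipped") <- n_skipped
  out
}

# BH adjustment when only the smallest p-values were kept but the total test
# count is known; exact for the retained set because unsaved p-values are
# all larger.
bh_adjust_partial <- function(p, m_total) {
  if (!length(p)) return(numeric(0))
  o <- order(p)
  ranked <- p[o] * m_total / seq_along(o)
  ranked <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(length(p))
  out[o] <- ranked
  out
}

#' P-value threshold equivalent to a target FDR
#'
#' Runs the BH step-up over the recorded p-values, counting unrecorded tests
#' (with p above any kept value) as non-discoveries, and returns the largest
#' p whose adjusted value is at or below `q_level`.
#'
#' @param pvals Recorded p-values (all tests, or the retained smallest ones).
#' @param m_total Total number of tests performed (default `length(pvals)`).
#' @param q_level Target FDR (default 0.01).
#' @return The p-value cutoff, or `NA_real_` when nothing passes.
#' @export
fdr_pvalue_cutoff <- function(pvals, m_total = length(pvals), q_level = 0.01) {
  if (!length(pvals)) return(NA_real_)
  ps <- sort(pvals)
  i <- seq_along(ps)
  pass <- ps <= q_level * i / m_total
  if (!any(pass)) return(NA_real_)
  ps[max(which(pass))]
}

#' Per-SNP summary of significant meQTL pairs
#'
#' @param pairs A meQTL pair tibble (typically filtered to significance).
#' @return Tibble per SNP: `n_sites`, `width_bp` (span of significant
#'   sites), `mean_abs_slope`.
#' @export
summarize_snp <- function(pairs) {
  dplyr::group_by(pairs, .data$snp_id) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      width_bp = max(.data$pos) - min(.data$pos),
      mean_abs_slope = mean(abs(.data$slope)),
      .groups = "drop"
    )
}

#' Index-SNP scan with cis/trans labels
#'
#' Tests the given SNPs against every site in the methylome (all p-values
#' retained), labelling a site cis when it lies on the SNP's chromosome
#' within `cis_window` bp, and trans otherwise (including other
#' chromosomes).
#'
#' @param m A smoothed [methylome()].
#' @param genotypes A `genotype_set`.
#' @param snp_ids SNPs to test (default: all).
#' @param covariates As in [meqtl_scan()].
#' @param cis_window Cis distance in bp (default 250 kb).
#' @return Pair tibble as [meqtl_scan()] plus a `cis_flag` column.
#' @export
index_snp_scan <- function(m, genotypes, snp_ids = genotypes$snps$snp_id,
                           covariates = NULL, cis_window = 250000) {
  sn <- genotypes$snps[genotypes$snps$snp_id %in% snp_ids, ]
  pairs <- tidyr::crossing(
    dplyr::select(sn, "snp_id", snp_pos = "pos", snp_chrom = "chrom"),
    tibble::tibble(site_idx = seq_len(nrow(m$sites)),
                   site_pos = m$sites$pos, chrom = m$sites$chrom,
                   context = m$sites$context)
  ) |>
    dplyr::mutate(distance = abs(.data$snp_pos - .data$site_pos))
  out <- meqtl_scan(m, genotypes,
                    covariates = covariates,
                    pairs = dplyr::mutate(pairs, chrom = .data$chrom),
                    p_keep = 1)
  snp_chrom <- setNames(sn$chrom, sn$snp_id)
  snp_pos <- setNames(sn$pos, sn$snp_id)
  dplyr::mutate(out, cis_flag = unname(ifelse(
    .data$chrom == snp_chrom[.data$snp_id] &
      abs(.data$pos - snp_pos[.data$snp_id]) <= cis_window, "cis", "trans")))
}

#' Genotype-by-modifier interaction scan
#'
#' For each pair, OLS of methylation on `[intercept, dosage, modifier,
#' dosage x modifier, covariates]`; reports the product-term estimate, t and
#' p.
#'
#' @param m A smoothed [methylome()].
#' @param genotypes A `genotype_set`.
#' @param pairs Pair tibble from [enumerate_cis_pairs()].
#' @param modifier Per-sample numeric modifier (age, neuronal fraction, an
#'   ancestry component, ...); must not be constant.
#' @param covariates Optional matrix as in [meqtl_scan()].
#' @return Tibble: snp_id, site_idx, pos, chrom, interaction, se, t, df, p,
#'   skip.
#' @export
interaction_scan <- function(m, genotypes, pairs, modifier, covariates = NULL) {
  if (is.null(m$smoothed)) rlang::abort("scan uses smoothed values")
  if (stats::var(modifier, na.rm = TRUE) == 0) {
    rlang::abort("`modifier` is constant")
  }
  C <- if (!is.null(covariates)) as.matrix(covariates)
  fit_one <- function(g, y) {
    ok <- !is.na(g) & !is.na(y) & !is.na(modifier)
    X <- cbind(1, g[ok], modifier[ok], g[ok] * modifier[ok],
               if (!is.null(C)) C[ok, , drop = FALSE])
    if (length(unique(g[ok])) < 2 || qr(X)$rank < ncol(X)) {
      return(c(NA, NA, NA, NA, NA))
    }
    fit <- stats::lm.fit(X, y[ok])
    df <- sum(ok) - fit$rank
    rss <- sum(fit$residuals^2)
    xtx_inv <- chol2inv(qr.R(fit$qr))
    se <- sqrt(rss / df * xtx_inv[4, 4])
    b <- fit$coefficients[[4]]
    t <- if (se > 0) b / se else 0
    c(b, se, t, df, 2 * stats::pt(-abs(t), df))
  }
  stats <- t(vapply(seq_len(nrow(pairs)), function(r) {
    fit_one(genotypes$dosage[, pairs$snp_id[r]], m$smoothed[pairs$site_idx[r], ])
  }, numeric(5)))
  tibble::tibble(
    snp_id = pairs$snp_id, site_idx = pairs$site_idx, pos = pairs$site_pos,
    chrom = pairs$chrom, interaction = stats[, 1], se = stats[, 2],
    t = stats[, 3], df = as.integer(stats[, 4]), p = stats[, 5],
    skip = ifelse(is.na(stats[, 1]), "collinear_or_constant", NA_character_)
  )
}
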