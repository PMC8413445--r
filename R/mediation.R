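#' Candidate SNP-CpG-feature triplets for mediation analysis
#'
#' For every SNP significant in both the eQTL and meQTL maps, emits one
#' triplet per (CpG, feature) combination whose expression-methylation
#' Pearson correlation passes the gate (`|r| > cor_threshold` by default;
#' `signed = TRUE` requires `r > cor_threshold`).
#'
#' @param eqtl Tibble of significant eQTL pairs (`snp_id`, `feature_id`).
#' @param meqtl Tibble of significant meQTL pairs (`snp_id`, `site_idx`).
#' @param expression Features x samples matrix, rownames = feature ids.
#' @param m A smoothed [methylome()] on the same samples (matched by
#'   position).
#' @param cor_threshold Correlation gate (default 0.3).
#' @param signed Use signed r instead of |r| (default FALSE).
#' @return Tibble: snp_id, site_idx, feature_id, cor_em.
#' @export
select_triplets <- function(eqtl, meqtl, expression, m, cor_threshold = 0.3,
                            signed = FALSE) {
  if (!identical(colnames(expression), m$samples)) {
    rlang::abort("expression and methylome must share the same samples in order")
  }
  shared <- intersect(unique(eqtl$snp_id), unique(meqtl$snp_id))
  out <- list()
  for (s in shared) {
    sites <- unique(meqtl$site_idx[meqtl$snp_id == s])
    feats <- unique(eqtl$feature_id[eqtl$snp_id == s])
    for (f in feats) {
      e <- expression[f, ]
      r <- vapply(sites, function(i) {
        suppressWarnings(stats::cor(e, m$smoothed[i, ],
                                    use = "pairwise.complete.obs"))
      }, numeric(1))
      gate <- if (signed) r > cor_threshold else abs(r) > cor_threshold
      gate[is.na(gate)] <- FALSE
      if (any(gate)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          snp_id = s, site_idx = sites[gate], feature_id = f,
          cor_em = r[gate])
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(snp_id = character(0), site_idx = integer(0),
                   feature_id = character(0), cor_em = numeric(0))
}

#' Mediation of an expression QTL by DNA methylation
#'
#' Fits the marginal model `expression ~ dosage + covariates` and the
#' adjusted model `expression ~ dosage + methylation + covariates` on the
#' identical sample set, and reports the proportion of the SNP coefficient
#' retained after adjustment. Retention below `prop_cut` (default 0.75,
#' i.e. >25% attenuation) is called mediation. Records with a sign flip
#' (ratio < 0) or a marginal coefficient below `beta_floor` (in units of the
#' expression SD) are flagged unstable and never called mediated.
#'
#' @param expression,dosage,methylation Per-sample vectors.
#' @param covariates Optional numeric matrix (samples x k).
#' @param prop_cut Mediation threshold on the retained proportion.
#' @param beta_floor Stability floor for |beta_marginal| in standardized
#'   units (default 1e-6).
#' @return One-row tibble: beta_marginal, beta_adjusted, prop_retained,
#'   mediated, unstable.
#' @export
mediation_fit <- function(expression, dosage, methylation, covariates = NULL,
                          prop_cut = 0.75, beta_floor = 1e-6) {
  ok <- !is.na(expression) & !is.na(dosage) & !is.na(methylation)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  e <- expression[ok]; g <- dosage[ok]; mm <- methylation[ok]
  if (length(unique(g)) < 2) rlang::abort("dosage is constant on the analysis samples")
  C <- if (!is.null(covariates)) as.matrix(covariates)[ok, , drop = FALSE]
  X1 <- cbind(1, g, C)
  X2 <- cbind(1, g, mm, C)
  if (qr(X2)$rank < ncol(X2)) rlang::abort("singular design in the adjusted model")
  b1 <- stats::lm.fit(X1, e)$coefficients[2]
  b2 <- stats::lm.fit(X2, e)$coefficients[2]
  prop <- b2 / b1
  unstable <- abs(b1) / stats::sd(e) < beta_floor || prop < 0
  tibble::tibble(
    beta_marginal = unname(b1), beta_adjusted = unname(b2),
    prop_retained = unname(prop),
    mediated = !unstable && prop < prop_cut,
    unstable = unstable
  )
}

#' Run the mediation model over a triplet table
#'
#' @param triplets Output of [select_triplets()].
#' @param expression Features x samples matrix.
#' @param m Smoothed [methylome()].
#' @param genotypes A `genotype_set`.
#' @param covariates,prop_cut,beta_floor As in [mediation_fit()].
#' @param feature_levels Optional named vector mapping feature_id to a level
#'   tag (gene/exon/junction).
#' @return The triplet tibble with the [mediation_fit()] columns appended.
#' @export
mediation_scan <- function(triplets, expression, m, genotypes,
                           covariates = NULL, prop_cut = 0.75,
                           beta_floor = 1e-6, feature_levels = NULL) {
  fits <- purrr::map(seq_len(nrow(triplets)), function(i) {
    mediation_fit(expression[triplets$feature_id[i], ],
                  genotypes$dosage[, triplets$snp_id[i]],
                  m$smoothed[triplets$site_idx[i], ],
                  covariates, prop_cut, beta_floor)
  })
  out <- dplyr::bind_cols(triplets, dplyr::bind_rows(fits))
  if (!is.null(feature_levels)) {
    out$level <- unname(feature_levels[out$feature_id])
  }
  out
}

#' Summarise mediation records per feature level
#'
#' @param records Output of [mediation_scan()] with a `level` column.
#' @return Tibble per level: n_triplets, n_mediated, median mediation
#'   proportion (1 - prop_retained) among mediated records.
#' @export
summarize_mediation <- function(records) {
  if (!"level" %in% names(records)) records$level <- "feature"
  med <- dplyr::filter(records, .data$mediated)
  if (!nrow(med)) {
    return(tibble::tibble(level = character(0), n_triplets = integer(0),
                          n_mediated = integer(0), median_mediation = numeric(0)))
  }
  dplyr::left_join(
    dplyr::count(records, .data$level, name = "n_triplets"),
    dplyr::group_by(med, .data$level) |>
      dplyr::summarise(n_mediated = dplyr::n(),
                       median_mediation = stats::median(1 - .data$prop_retained),
                       .groups = "drop"),
    by = "level"
  ) |>
    dplyr::filter(!is.na(.data$n_mediated))
}
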