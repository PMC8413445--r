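#' Scree plot of methylation principal components
#'
#' @param object A [meth_pca()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_pca
#' @export
autoplot.meth_pca <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = d$component)
  ggplot2::ggplot(d, ggplot2::aes(.data$component, .data$var_explained)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "variance explained") +
    ggplot2::theme_minimal()
}

#' Volcano-style view of a meQTL scan
#'
#' Per-allele slope against -log10 p, coloured by context.
#'
#' @param pairs Pair tibble from [meqtl_scan()].
#' @param p_cutoff Optional p-value cutoff drawn as a line.
#' @return A ggplot.
#' @export
plot_meqtl_volcano <- function(pairs, p_cutoff = NULL) {
  p <- ggplot2::ggplot(pairs,
                       ggplot2::aes(.data$slope, -log10(.data$p),
                                    colour = .data$context)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::labs(x = "methylation change per allele",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(p_cutoff) && !is.na(p_cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(p_cutoff),
                                 linetype = "dashed")
  }
  p
}

#' Methylation against dosage at one SNP-site pair
#'
#' @param m A smoothed [methylome()].
#' @param genotypes A `genotype_set`.
#' @param snp_id,site_idx The pair to display.
#' @return A ggplot with per-genotype boxplots.
#' @export
plot_pair <- function(m, genotypes, snp_id, site_idx) {
  d <- tibble::tibble(
    dosage = factor(genotypes$dosage[, snp_id], levels = 0:2),
    methylation = m$smoothed[site_idx, ]
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$dosage, .data$methylation)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_jitter(width = 0.15, size = 0.6, alpha = 0.5) +
    ggplot2::labs(x = sprintf("%s (alt allele count)", snp_id),
                  y = sprintf("smoothed methylation, site %d", site_idx)) +
    ggplot2::theme_minimal()
}

#' Enrichment plot for partitioned heritability
#'
#' @param object A `partitioned_h2` result.
#' @param ... Unused.
#' @return A ggplot of enrichment with jackknife error bars.
#' @method autoplot partitioned_h2
#' @export
autoplot.partitioned_h2 <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$annotation, .data$enrichment)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$enrichment - .data$enrichment_se,
      ymax = .data$enrichment + .data$enrichment_se), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "heritability enrichment") +
    ggplot2::theme_minimal()
}
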