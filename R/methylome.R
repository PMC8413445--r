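#' Methylome container
#'
#' Holds per-site methylated/total read counts (sites x samples) together
#' with the site table and, once [smooth_methylome()] has run, smoothed
#' methylation fractions. Sites are always sorted by (chrom, pos).
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `context`
#'   ("CpG"/"CpH") and optionally `strand`.
#' @param methylated,coverage Integer matrices, sites x samples, with
#'   `methylated <= coverage` elementwise.
#' @param samples Character vector of sample ids (columns).
#' @param smoothed Optional numeric matrix of smoothed fractions in [0, 1].
#' @return An object of class `methylome`.
#' @export
methylome <- function(sites, methylated, coverage, samples,
                      smoothed = NULL) {
  sites <- tibble::as_tibble(sites)
  if (!all(c("chrom", "pos", "context") %in% names(sites))) {
    rlang::abort("`sites` needs columns chrom, pos, context.")
  }
  if (!"strand" %in% names(sites)) sites$strand <- "*"
  if (any(sites$pos < 1)) rlang::abort("site positions are 1-based; pos >= 1 required.")
  ord <- order(sites$chrom, sites$pos)
  if (any(ord != seq_along(ord))) {
    sites <- sites[ord, ]
    methylated <- methylated[ord, , drop = FALSE]
    coverage <- coverage[ord, , drop = FALSE]
    if (!is.null(smoothed)) smoothed <- smoothed[ord, , drop = FALSE]
  }
  stopifnot(
    nrow(methylated) == nrow(sites), nrow(coverage) == nrow(sites),
    ncol(methylated) == length(samples), ncol(coverage) == length(samples)
  )
  if (any(methylated > coverage)) {
    rlang::abort("methylated counts exceed coverage; invalid methylome.")
  }
  if (any(methylated < 0) || any(coverage < 0)) {
    rlang::abort("negative counts; invalid methylome.")
  }
  if (!is.null(smoothed)) {
    stopifnot(dim(smoothed)[1] == nrow(sites), dim(smoothed)[2] == length(samples))
    assert_fraction(smoothed[is.finite(smoothed)], "smoothed")
  }
  colnames(methylated) <- samples
  colnames(coverage) <- samples
  structure(
    list(sites = sites, methylated = methylated, coverage = coverage,
         samples = samples, smoothed = smoothed),
    class = "methylome"
  )
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> %d sites (%d CpG, %d CpH) x %d samples%s\n",
              nrow(x$sites), sum(x$sites$context == "CpG"),
              sum(x$sites$context == "CpH"), length(x$samples),
              if (is.null(x$smoothed)) "" else ", smoothed"))
  invisible(x)
}

#' @export
dim.methylome <- function(x) c(nrow(x$sites), length(x$samples))

#' Raw methylation fractions (methylated / coverage)
#'
#' Cells with zero coverage are `NA`.
#'
#' @param m A [methylome()].
#' @return Numeric matrix, sites x samples.
#' @export
raw_fractions <- function(m) {
  stopifnot(inherits(m, "methylome"))
  out <- m$methylated / m$coverage
  out[m$coverage == 0] <- NA_real_
  out
}

#' Site table of a methylome as a tibble
#'
#' @param x A [methylome()].
#' @param ... Unused.
#' @return The site tibble with a `site_idx` column.
#' @method tidy methylome
#' @export
tidy.methylome <- function(x, ...) {
  dplyr::mutate(x$sites, site_idx = dplyr::row_number(), .before = 1)
}

#' One-row summary of a methylome
#'
#' @param x A [methylome()].
#' @param ... Unused.
#' @return Tibble with site/sample counts, mean coverage, and the fraction
#'   of highly (>80%) methylated sites.
#' @method glance methylome
#' @export
glance.methylome <- function(x, ...) {
  fr <- raw_fractions(x)
  site_mean <- rowMeans(fr, na.rm = TRUE)
  tibble::tibble(
    n_sites = nrow(x$sites),
    n_cpg = sum(x$sites$context == "CpG"),
    n_cph = sum(x$sites$context == "CpH"),
    n_samples = length(x$samples),
    mean_coverage = mean(x$coverage),
    frac_high = mean(site_mean > 0.8, na.rm = TRUE),
    frac_low = mean(site_mean < 0.2, na.rm = TRUE),
    smoothed = !is.null(x$smoothed)
  )
}
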