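#' Coverage filter for CpG sites
#'
#' Retains CpG sites whose mean coverage across samples meets `min_cov`
#' (the `rule = "mean"` default); `rule = "all"` demands the threshold in
#' every sample instead. Non-CpG sites pass through untouched. Idempotent.
#'
#' @param m A [methylome()].
#' @param min_cov Coverage threshold (default 3).
#' @param rule "mean" (default) or "all" (per-sample).
#' @return A filtered [methylome()]; warns when no CpG survives.
#' @export
filter_cpg <- function(m, min_cov = 3, rule = c("mean", "all")) {
  stopifnot(inherits(m, "methylome"))
  rule <- match.arg(rule)
  is_cpg <- m$sites$context == "CpG"
  ok <- if (rule == "mean") rowMeans(m$coverage) >= min_cov
        else apply(m$coverage, 1, function(v) all(v >= min_cov))
  keep <- !is_cpg | ok
  if (!any(keep & is_cpg) && any(is_cpg)) {
    rlang::warn("no CpG site passes the coverage filter")
  }
  subset_methylome(m, keep)
}

#' Coverage/non-zero filter for CpH sites
#'
#' Retains a CpH site when at least `min_nonzero_frac` of samples jointly
#' show coverage >= `min_cov` (i.e. > 3 by default) and a non-zero
#' methylated count. Non-CpH sites pass through. Idempotent.
#'
#' @param m A [methylome()].
#' @param min_cov Per-sample coverage threshold (default 4, i.e. coverage
#'   > 3).
#' @param min_nonzero_frac Required fraction of qualifying samples.
#' @return A filtered [methylome()].
#' @export
filter_cph <- function(m, min_cov = 4, min_nonzero_frac = 0.5) {
  stopifnot(inherits(m, "methylome"))
  is_cph <- m$sites$context == "CpH"
  qual <- (m$coverage >= min_cov) & (m$methylated > 0)
  ok <- rowMeans(qual) >= min_nonzero_frac
  subset_methylome(m, !is_cph | ok)
}

#' Remove sites falling in blacklist intervals
#'
#' Intervals follow the BED convention (0-based half-open, as returned by
#' [read_bed()]); site positions are 1-based. A site at 1-based position p is
#' excluded when `start < p <= end` for any interval on its chromosome.
#' Input order is preserved.
#'
#' @param m A [methylome()] or a site tibble with `chrom` and `pos`.
#' @param blacklist Tibble with `chrom`, `start`, `end` (BED coordinates).
#' @return Object of the same type with blacklisted sites removed.
#' @export
exclude_blacklist <- function(m, blacklist) {
  sites <- if (inherits(m, "methylome")) m$sites else tibble::as_tibble(m)
  if (nrow(blacklist) == 0) {
    return(m)
  }
  hit <- rep(FALSE, nrow(sites))
  for (ch in unique(blacklist$chrom)) {
    bl <- blacklist[blacklist$chrom == ch, ]
    on_ch <- which(sites$chrom == ch)
    if (!length(on_ch)) next
    p <- sites$pos[on_ch]
    # sorted interval stab: count of starts < p minus count of ends < p
    n_open <- findInterval(p - 1, sort(bl$start))   # starts <= p-1 i.e. start < p
    n_closed <- findInterval(p - 1, sort(bl$end))   # ends <= p-1 i.e. end < p
    hit[on_ch] <- n_open > n_closed
  }
  if (inherits(m, "methylome")) subset_methylome(m, !hit) else sites[!hit, ]
}

subset_methylome <- function(m, keep) {
  methylome(m$sites[keep, , drop = FALSE],
            m$methylated[keep, , drop = FALSE],
            m$coverage[keep, , drop = FALSE],
            m$samples,
            if (is.null(m$smoothed)) NULL else m$smoothed[keep, , drop = FALSE])
}
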