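#' BSmooth-style local smoothing of methylation fractions
#'
#' At each cytosine a local linear model is fitted to the raw methylation
#' fractions of neighbouring sites, weighted by the product of a tricube
#' distance kernel and read coverage (an approximation to local-likelihood
#' binomial smoothing). The window at a site is the smallest symmetric
#' distance window that contains at least `min_sites` sites and spans at
#' least `min_width` bp; near chromosome ends the window truncates
#' naturally. The fitted value at the site, clipped to [0, 1], is the
#' smoothed methylation level; zero-coverage sites contribute no weight but
#' still receive the local fit (imputation).
#'
#' @param methylated,coverage Integer vectors (per-site counts, one sample)
#'   or matrices (sites x samples; all samples share the window geometry, so
#'   matrix input is much faster).
#' @param positions Sorted 1-based bp positions, one chromosome.
#' @param min_sites Minimum sites per window (default 70).
#' @param min_width Minimum total window span in bp (default 2000).
#' @return Numeric vector/matrix of smoothed fractions, same shape as input.
#' @export
smooth_sample <- function(methylated, coverage, positions,
                          min_sites = 70, min_width = 2000) {
  meth <- as.matrix(methylated)
  cov <- as.matrix(coverage)
  stopifnot(nrow(meth) == length(positions), all(dim(meth) == dim(cov)))
  if (is.unsorted(positions, strictly = FALSE)) {
    rlang::abort("`positions` must be sorted ascending.")
  }
  ns <- length(positions)
  k <- min(min_sites, ns)
  if (ns < min_sites) {
    rlang::warn(sprintf(
      "only %d sites on chromosome (< min_sites = %d); using the whole chromosome",
      ns, min_sites))
  }

  frac <- ifelse(cov > 0, meth / cov, 0)
  w_cov <- cov
  out <- matrix(NA_real_, ns, ncol(meth))

  for (i in seq_len(ns)) {
    # smallest symmetric distance window holding >= k sites: the k nearest
    # neighbours of a site are contiguous in a sorted vector
    lo <- max(1L, i - k + 1L)
    hi <- min(ns - k + 1L, i)
    j <- lo:hi
    h_knn <- min(pmax(positions[i] - positions[j],
                      positions[j + k - 1L] - positions[i]))
    h <- max(h_knn, min_width / 2)
    l <- findInterval(positions[i] - h, positions, left.open = TRUE) + 1L
    r <- findInterval(positions[i] + h, positions)
    idx <- l:r

    x <- positions[idx] - positions[i]
    tric <- (1 - pmin(abs(x) / (h * 1.0001), 1)^3)^3
    w <- tric * w_cov[idx, , drop = FALSE]
    y <- frac[idx, , drop = FALSE]

    W <- colSums(w)
    Sx <- colSums(w * x)
    Sy <- colSums(w * y)
    Sxx <- colSums(w * x^2)
    Sxy <- colSums(w * x * y)
    denom <- W * Sxx - Sx^2
    fit <- (Sxx * Sy - Sx * Sxy) / denom
    flat <- !is.finite(fit) | denom <= .Machine$double.eps * pmax(W * Sxx, 1)
    fit[flat] <- (Sy / W)[flat]
    fit[W == 0] <- NA_real_
    out[i, ] <- pmin(pmax(fit, 0), 1)
  }
  if (is.null(dim(methylated))) out[, 1] else out
}

#' Smooth every sample of a methylome
#'
#' Runs [smooth_sample()] per chromosome across all samples (post-filter
#' sites, CpG and CpH alike).
#'
#' @param m A [methylome()].
#' @inheritParams smooth_sample
#' @return The methylome with its `smoothed` matrix filled in.
#' @export
smooth_methylome <- function(m, min_sites = 70, min_width = 2000) {
  stopifnot(inherits(m, "methylome"))
  sm <- matrix(NA_real_, nrow(m$sites), length(m$samples))
  for (ch in unique(m$sites$chrom)) {
    sel <- which(m$sites$chrom == ch)
    sm[sel, ] <- smooth_sample(m$methylated[sel, , drop = FALSE],
                               m$coverage[sel, , drop = FALSE],
                               m$sites$pos[sel], min_sites, min_width)
  }
  m$smoothed <- sm
  colnames(m$smoothed) <- m$samples
  m
}
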