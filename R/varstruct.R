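#' Indices of the most variable sites
#'
#' Ranks sites by across-sample variance of the smoothed methylation levels
#' (descending), breaking ties by genomic order.
#'
#' @param m A smoothed [methylome()].
#' @param n_top Number of sites to return; capped at the site count with a
#'   warning.
#' @return Integer site indices, most variable first.
#' @export
top_variable_sites <- function(m, n_top) {
  stopifnot(inherits(m, "methylome"))
  if (is.null(m$smoothed)) rlang::abort("smoothed values required; run smooth_methylome()")
  v <- apply(m$smoothed, 1, stats::var)
  if (n_top > length(v)) {
    rlang::warn("n_top exceeds site count; returning all sites")
    n_top <- length(v)
  }
  order(-v, seq_along(v))[seq_len(n_top)]
}

#' Covariance PCA of methylation (centred SVD)
#'
#' Principal components of the samples-by-sites matrix after centring each
#' site, computed by singular value decomposition without standardisation.
#' Component signs are fixed by making the largest-magnitude site loading of
#' each component positive.
#'
#' @param values Sites x samples numeric matrix (e.g. `m$smoothed[idx, ]`).
#' @param k Number of components to keep (default all).
#' @return A `meth_pca` object: `scores` (samples x k), `var_explained`
#'   (fractions, non-increasing), `sdev`, and the number of sites used.
#' @export
meth_pca <- function(values, k = NULL) {
  x <- t(values)                      # samples x sites
  if (nrow(x) < 2) rlang::abort("PCA needs >= 2 samples")
  x <- sweep(x, 2, colMeans(x))
  s <- svd(x)
  tot <- sum(s$d^2)
  ve <- if (tot > 0) s$d^2 / tot else rep(0, length(s$d))
  # sign convention: largest |loading| positive
  for (j in seq_along(s$d)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  scores <- s$u %*% diag(s$d, length(s$d))
  k <- min(k %||% ncol(scores), ncol(scores))
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores[, seq_len(k), drop = FALSE],
                 var_explained = ve[seq_len(k)],
                 sdev = s$d[seq_len(k)] / sqrt(max(1, nrow(x) - 1)),
                 n_sites = ncol(x)),
            class = "meth_pca")
}

#' @export
print.meth_pca <- function(x, ...) {
  cat(sprintf("<meth_pca> %d components over %d sites; PC1 explains %.1f%%\n",
              ncol(x$scores), x$n_sites, 100 * x$var_explained[1]))
  invisible(x)
}

#' @method tidy meth_pca
#' @export
tidy.meth_pca <- function(x, ...) {
  tibble::tibble(component = colnames(x$scores),
                 var_explained = x$var_explained,
                 sdev = x$sdev)
}

#' @method glance meth_pca
#' @export
glance.meth_pca <- function(x, ...) {
  tibble::tibble(n_components = ncol(x$scores), n_sites = x$n_sites,
                 pc1_var = x$var_explained[1])
}

#' Sequential (Type-I) ANOVA variance decomposition for one site
#'
#' Fits `lm(site_values ~ covariate1 + covariate2 + ...)` in the stated
#' column order and reports each term's sequential sum of squares as a
#' fraction of the total, with the residual completing to 1. Collinear
#' covariates are dropped with a warning and recorded.
#'
#' @param site_values Numeric vector, one value per sample.
#' @param covariates Data frame of covariates whose column order defines the
#'   sequential decomposition; factors/characters are expanded by `lm`.
#' @return A tibble with `term`, `fraction` (the residual is the last row)
#'   and attribute `dropped` naming any dropped terms.
#' @export
variance_components <- function(site_values, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(length(site_values) == nrow(covariates))
  dat <- cbind(data.frame(.y = site_values), covariates)
  fit <- stats::lm(.y ~ ., data = dat)
  dropped <- names(which(is.na(coef(fit))))
  if (length(dropped)) {
    rlang::warn(paste("collinear terms dropped:", paste(dropped, collapse = ", ")))
  }
  a <- stats::anova(fit)
  ss <- a[["Sum Sq"]]
  total <- sum(ss)
  frac <- if (total > 0) ss / total else rep(0, length(ss))
  out <- tibble::tibble(term = rownames(a), fraction = frac)
  attr(out, "dropped") <- dropped
  attr(out, "order") <- names(covariates)
  out
}
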