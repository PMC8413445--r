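#' Site-wise linear models for differential methylation
#'
#' OLS of each site's smoothed methylation on a design matrix whose first
#' non-intercept column is the outcome of interest (age, diagnosis
#' indicator, ...), with the remaining columns as adjustment covariates.
#' Residual df is shared across sites.
#'
#' @param m A smoothed [methylome()].
#' @param design Numeric design matrix (samples x p) including an intercept
#'   column; must be full rank.
#' @param coef Name or index of the coefficient of interest (default 2).
#' @return Tibble per site: site_idx, coef (estimate), s2 (residual
#'   variance), df, scale (unscaled coefficient variance factor).
#' @export
fit_site_models <- function(m, design, coef = 2) {
  stopifnot(inherits(m, "methylome"))
  if (is.null(m$smoothed)) rlang::abort("smoothed values required")
  X <- as.matrix(design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) rlang::abort("design matrix is rank deficient")
  n <- nrow(X)
  df <- n - ncol(X)
  xtx_inv <- chol2inv(qr.R(qx))
  j <- if (is.character(coef)) match(coef, colnames(X)) else coef
  # all sites at once: B = (X'X)^-1 X'Y'
  Y <- t(m$smoothed)                       # samples x sites
  B <- xtx_inv %*% crossprod(X, Y)         # p x sites
  res <- Y - X %*% B
  s2 <- colSums(res^2) / df
  tibble::tibble(site_idx = seq_len(ncol(Y)), coef = B[j, ], s2 = s2,
                 df = df, scale = xtx_inv[j, j])
}

#' Empirical-Bayes moderation of site variances (moderated t)
#'
#' Estimates a scaled inverse chi-square prior (d0, s0^2) for the residual
#' variances by matching moments of log s^2 (digamma/trigamma relations,
#' with the trigamma equation inverted by Newton iteration), shrinks each
#' site's variance to the posterior s_tilde^2 = (d0 s0^2 + d s^2)/(d0 + d),
#' and recomputes t and p on d0 + d degrees of freedom. When the observed
#' log-variances are underdispersed relative to pure chi-square noise the
#' prior is infinite and all posterior variances equal s0^2.
#'
#' @param fits Output of [fit_site_models()].
#' @return A `moderated_fit` object: the input tibble plus s2_post, t_mod,
#'   p, q, and attributes d0 and s0_2.
#' @export
ebayes_moderate <- function(fits) {
  s2 <- fits$s2
  d <- fits$df[1]
  keep <- s2 > 0
  if (sum(keep) < 2) rlang::abort("need at least two sites with positive variance")
  z <- log(s2[keep])
  # log s^2 = log s0^2 + [log chi^2_d / d] noise; match mean and variance
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- mean(e)
  vv <- stats::var(e)
  excess <- vv - trigamma(d / 2)
  if (vv < .Machine$double.eps) {
    # no spread at all in the observed variances: point-mass prior at the
    # common value, so posterior variances (and t) are unchanged
    d0 <- Inf
    s0_2 <- exp(mean(z))
  } else if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_2 <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(ev)
  }
  s2_post <- if (is.finite(d0)) (d0 * s0_2 + d * s2) / (d0 + d)
             else rep(s0_2, length(s2))
  df_total <- d + d0
  t_mod <- fits$coef / sqrt(s2_post * fits$scale)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- dplyr::mutate(fits, s2_post = s2_post, t_mod = t_mod, p = p,
                       q = bh_fdr(p))
  structure(out, class = c("moderated_fit", class(out)),
            d0 = d0, s0_2 = s0_2, df_total = df_total)
}

# Solve trigamma(y) = x by Newton iteration on 1/y (limma-style update),
# tolerance 1e-8.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(d0 = attr(x, "d0"), s0_2 = attr(x, "s0_2"),
                 df_total = attr(x, "df_total"), n_sites = nrow(x),
                 n_fdr05 = sum(x$q < 0.05, na.rm = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `p.adjust(method = "BH")`.
#'
#' @param pvals P-values.
#' @return Adjusted values (monotone, capped at 1).
#' @export
bh_fdr <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}
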