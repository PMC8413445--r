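#' Storey estimate of the null proportion pi0 (and pi1 = 1 - pi0)
#'
#' Computes pi0_hat(lambda) = #\{p > lambda\} / (m (1 - lambda)) over the
#' lambda grid, smooths it with a cubic smoothing spline (df = 3) and takes
#' the smoothed value at the largest lambda, clamped to [0, 1]. With
#' `method = "fixed"` the estimate at lambda = 0.5 is used instead (stabler
#' for small m).
#'
#' @param pvals P-values in [0, 1].
#' @param lambda_grid Evaluation grid (default 0.05 to 0.95 by 0.05).
#' @param method "smoother" (default) or "fixed".
#' @return A `pi1_estimate`: tibble row with pi0, pi1, method, n_pvals, and
#'   the raw (unclamped) estimate in `pi0_raw`.
#' @export
storey_pi0 <- function(pvals, lambda_grid = seq(0.05, 0.95, by = 0.05),
                       method = c("smoother", "fixed")) {
  method <- match.arg(method)
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) rlang::abort("no p-values supplied")
  if (length(pvals) < 100) {
    rlang::warn("fewer than 100 p-values; pi0 estimate will be unstable")
  }
  m <- length(pvals)
  pi0_l <- vapply(lambda_grid, function(l) sum(pvals > l) / (m * (1 - l)),
                  numeric(1))
  raw <- if (method == "smoother" && length(lambda_grid) >= 4) {
    sp <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
    stats::predict(sp, x = max(lambda_grid))$y
  } else {
    pi0_l[which.min(abs(lambda_grid - 0.5))]
  }
  pi0 <- min(max(raw, 0), 1)
  structure(tibble::tibble(pi0 = pi0, pi1 = 1 - pi0, pi0_raw = raw,
                           method = method, n_pvals = m),
            class = c("pi1_estimate", "tbl_df", "tbl", "data.frame"),
            lambda_grid = lambda_grid)
}

#' Cross-dataset sharing of meQTLs (pi1)
#'
#' Takes the discovery-significant SNP-site pairs, looks their p-values up
#' in the replication scan regardless of replication significance, and runs
#' [storey_pi0()] on those p-values. Pairs absent from the replication scan
#' are counted and reported.
#'
#' @param discovery Pair tibble of discovery-significant meQTLs (snp_id,
#'   site identified by chrom+pos).
#' @param replication Pair tibble with replication statistics for (at least)
#'   those pairs, with a `p` column.
#' @param method Passed to [storey_pi0()].
#' @return A `pi1_estimate` with additional columns `n_discovery` and
#'   `n_matched`.
#' @export
pi1_sharing <- function(discovery, replication, method = "smoother") {
  key <- function(d) paste(d$snp_id, d$chrom, d$pos)
  idx <- match(key(discovery), key(replication))
  matched <- !is.na(idx)
  if (!any(matched)) rlang::abort("no discovery pair found in the replication set")
  est <- storey_pi0(replication$p[idx[matched]], method = method)
  est$n_discovery <- nrow(discovery)
  est$n_matched <- sum(matched)
  est
}
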