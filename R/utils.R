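# Internal helpers shared across the pipeline.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Convert 0-based half-open intervals to 1-based inclusive
#'
#' All site positions in this package are 1-based; BED input is 0-based
#' half-open. This is the single conversion point.
#'
#' @param start,end Numeric vectors of BED start/end coordinates.
#' @return A tibble with columns `start1` and `end1` (1-based inclusive).
#' @export
bed_to_1based <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (any(end <= start)) {
    rlang::abort("BED intervals must satisfy end > start (0-based half-open).")
  }
  tibble::tibble(start1 = start + 1L, end1 = end)
}

assert_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    rlang::abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

# Zero-truncated Poisson rate whose truncated mean equals `target_mean`.
ztpois_lambda <- function(target_mean) {
  stopifnot(target_mean > 1)
  f <- function(l) l / (1 - exp(-l)) - target_mean
  stats::uniroot(f, lower = 1e-8, upper = target_mean + 10)$root
}

rztpois <- function(n, lambda) {
  # inverse-CDF on the truncated support; exact, vectorised
  u <- stats::runif(n)
  stats::qpois(exp(-lambda) + u * (1 - exp(-lambda)), lambda)
}
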