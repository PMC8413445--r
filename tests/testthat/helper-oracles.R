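# Independent brute-force oracles used across the test files. These are
# deliberately written with different algorithms / numerical paths than the
# package implementations (explicit normal equations, double loops, grid
# searches) so agreement is evidence of correctness, not of shared code.

# --- ordinary least squares via explicit normal equations -------------------
# Returns estimate, se, t, df, p for the coefficient in column `j` of X.
oracle_ols <- function(X, y, j = 2) {
  X <- as.matrix(X)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * xtx_inv[j, j])
  tval <- beta[j] / se
  list(slope = unname(beta[j]), se = unname(se), t = unname(tval), df = df,
       p = 2 * pt(-abs(tval), df), beta = as.vector(beta))
}

# --- Benjamini-Hochberg step-up, textbook form ------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest p downwards
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Largest p with BH-adjusted value <= q when `m_total` tests were performed
# (unrecorded tests all have larger p).
oracle_bh_cutoff <- function(p, m_total, q) {
  ps <- sort(p)
  pass <- ps <= q * seq_along(ps) / m_total
  if (!any(pass)) NA_real_ else ps[max(which(pass))]
}

# --- cis pair enumeration, O(n*m) double loop -------------------------------
oracle_pairs <- function(snps, sites, window) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(sites))) {
      if (snps$chrom[i] == sites$chrom[j] &&
          abs(snps$pos[i] - sites$pos[j]) <= window) {
        out[[length(out) + 1L]] <- data.frame(
          snp_id = snps$snp_id[i], site_idx = j)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(snp_id = character(0), site_idx = integer(0))
}

# --- exhaustive gDMR run enumeration ----------------------------------------
oracle_gdmrs <- function(t, positions, cutoff, maxgap, min_sites) {
  n <- length(t)
  regions <- list()
  i <- 1
  while (i <= n) {
    ti <- t[i]
    if (!is.na(ti) && abs(ti) >= cutoff) {
      s <- sign(ti)
      j <- i
      while (j < n &&
             !is.na(t[j + 1]) && abs(t[j + 1]) >= cutoff &&
             sign(t[j + 1]) == s &&
             positions[j + 1] - positions[j] <= maxgap) {
        j <- j + 1
      }
      if (j - i + 1 >= min_sites) {
        regions[[length(regions) + 1L]] <- data.frame(
          start = positions[i], end = positions[j], n_sites = j - i + 1,
          mean_t = mean(t[i:j]), sign = if (s > 0) "+" else "-")
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(regions)) do.call(rbind, regions) else
    data.frame(start = numeric(0), end = numeric(0), n_sites = integer(0),
               mean_t = numeric(0), sign = character(0))
}

# --- LD scores, double loop over SNP pairs ----------------------------------
oracle_ld_scores <- function(dosage, pos, ann, window) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  L <- matrix(0, m, ncol(ann))
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (abs(pos[k] - pos[j]) <= window) {
        r <- cor(dosage[, j], dosage[, k])
        r2 <- min(r^2, 1)
        r2a <- r2 - (1 - r2) / (n - 2)
        for (c in seq_len(ncol(ann))) if (ann[k, c]) L[j, c] <- L[j, c] + r2a
      }
    }
  }
  colnames(L) <- colnames(ann)
  L
}

# --- GRM, elementwise loop --------------------------------------------------
oracle_grm <- function(dosage) {
  p <- colMeans(dosage) / 2
  keep <- p > 0 & p < 1
  d <- dosage[, keep, drop = FALSE]
  p <- p[keep]
  n <- nrow(d)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- sum((d[i, ] - 2 * p) * (d[j, ] - 2 * p) / (2 * p * (1 - p)))
    }
  }
  A / ncol(d)
}

# --- sequential (Type-I) variance fractions via Gram-Schmidt ----------------
# Projects y on the column blocks of the expanded design in order; each
# term's fraction is the squared norm captured by its block after removing
# everything before it, over the total (centred) sum of squares.
oracle_seq_anova <- function(y, covariates) {
  yc <- y - mean(y)
  total <- sum(yc^2)
  basis <- matrix(1, length(y), 1)  # intercept already removed via centring
  fracs <- numeric(ncol(covariates))
  for (k in seq_len(ncol(covariates))) {
    v <- covariates[[k]]
    block <- if (is.numeric(v)) matrix(v, ncol = 1) else
      model.matrix(~ f, data.frame(f = factor(v)))[, -1, drop = FALSE]
    new_basis <- cbind(basis, block)
    fit_before <- qr.fitted(qr(basis), y)
    fit_after <- qr.fitted(qr(new_basis), y)
    fracs[k] <- sum((fit_after - fit_before)^2) / total
    basis <- new_basis
  }
  resid_frac <- sum((y - qr.fitted(qr(basis), y))^2) / total
  c(fracs, resid_frac)
}

# --- restricted (REML) profile log-likelihood, independent path -------------
# Full-matrix formula: -1/2 [ log|V| + log|X'V^-1 X| + y'Py ] with the total
# variance profiled out analytically; computed with dense solves rather than
# the package's eigen-rotation.
oracle_reml_nll <- function(y, A, X, h2) {
  n <- length(y)
  r <- qr(X)$rank
  V0 <- h2 * A + (1 - h2) * diag(n)
  Vi <- solve(V0)
  XtVX <- t(X) %*% Vi %*% X
  P0 <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  quad <- drop(t(y) %*% P0 %*% y)
  s2 <- quad / (n - r)
  0.5 * (determinant(V0)$modulus + determinant(XtVX)$modulus +
           (n - r) * log(s2) + (n - r))
}
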