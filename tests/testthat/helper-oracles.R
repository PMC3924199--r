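# Independent oracles used to validate the package's computational paths.
# These deliberately re-derive results from first principles (direct
# probability arithmetic, naive double loops, published formulas) and stay
# independent of the implementation they check.

# direct (non-log) conditional null distribution of Y1 given Y1 + Y0 = s
oracle_cond_dist <- function(s, n0, n1, mu0, w, phi) {
  a <- 0:s
  f1 <- if (phi == 0) dpois(a, n1 * w * mu0)
        else dnbinom(a, mu = n1 * w * mu0, size = n1 / phi)
  f0 <- if (phi == 0) dpois(s - a, n0 * mu0)
        else dnbinom(s - a, mu = n0 * mu0, size = n0 / phi)
  j <- f1 * f0
  j / sum(j)
}

# brute-force small-probabilities p-value by direct enumeration
oracle_pvalue <- function(y1, y0, n0, n1, mu0, w, phi, tie_tol = 1e-7) {
  s <- y1 + y0
  if (s == 0) return(1)
  q <- oracle_cond_dist(s, n0, n1, mu0, w, phi)
  sum(q[q <= q[y1 + 1] * (1 + tie_tol)])
}

# naive double-sum power: loop over all (y1, y0) pairs on the truncated grid
oracle_power_naive <- function(n, rho, mu0, phi, w, alpha, epsilon = 1e-10) {
  qb <- function(mu, ph, eps) {
    if (ph == 0) qpois(1 - eps, mu) else qnbinom(1 - eps, mu = mu, size = 1 / ph)
  }
  ph <- phi / n
  B1 <- qb(n * w * rho * mu0, ph, epsilon / 2)
  B0 <- qb(n * mu0, ph, epsilon / 2)
  dalt <- function(y, mu) if (ph == 0) dpois(y, mu) else
    dnbinom(y, mu = mu, size = 1 / ph)
  pow <- 0
  for (y1 in 0:B1) for (y0 in 0:B0) {
    if (oracle_pvalue(y1, y0, n, n, mu0, w, phi) < alpha)
      pow <- pow + dalt(y1, n * w * rho * mu0) * dalt(y0, n * mu0)
  }
  pow
}

# direct implementation of TMM normalization factors (30% M trim, 5% A trim,
# reference = sample whose upper quartile of count/libsize is closest to the
# mean upper quartile), returned on the edgeR scale (geometric mean 1)
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j] / lib[j]
    rf <- counts[, ref] / lib[ref]
    keep0 <- obs > 0 & rf > 0
    M <- log2(obs[keep0] / rf[keep0])
    A <- 0.5 * log2(obs[keep0] * rf[keep0])
    v <- (lib[j] - counts[keep0, j]) / (lib[j] * counts[keep0, j]) +
      (lib[ref] - counts[keep0, ref]) / (lib[ref] * counts[keep0, ref])
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# direct Storey q-values: q_i = min over p_j >= p_i of pi0 m p_j / rank(p_j)
oracle_qvalue <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, max(1 / m, sum(p > lambda) / (m * (1 - lambda))))
  r <- rank(p, ties.method = "max")
  vapply(p, function(pi)
    min(1, min(pi0 * m * p[p >= pi] / r[p >= pi])), numeric(1))
}
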