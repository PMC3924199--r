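# Exact power of the NB exact test. Under the alternative the group sums
# are Y1 ~ NB(n1 * w * rho * mu0, phi/n1) and Y0 ~ NB(n0 * mu0, phi/n0);
# power is the alternative probability of the event {p(y1, y0) < alpha},
# computed as a truncated double sum over outcome pairs.

#' Exact power of the NB exact test
#'
#' Power `xi(n, rho, mu0, phi, w, alpha)` of the two-sided exact test at
#' significance level `alpha` when the true fold change is `rho`. The double
#' sum over outcome pairs is organised by total `s = y1 + y0`: for each
#' total, the conditional null distribution is built once, the rejection set
#' `{a : p(a, s - a) < alpha}` is identified, and the joint alternative mass
#' of that set is accumulated. This costs O(S^2) conditional work over the
#' truncated grid instead of the O(S^3) of per-pair p-values, which is what
#' makes designs with several hundred samples per group tractable.
#'
#' Truncation: each alternative marginal is cut at [nb_tail_bound()] with
#' tail mass `epsilon/2`; since the rejection indicator is bounded by 1, the
#' absolute truncation error is at most `epsilon`.
#'
#' Unbalanced designs use `n0 = n` and `n1 = k * n`.
#'
#' @param n per-group sample size of the control group (balanced when
#'   `k = 1`).
#' @param rho positive fold change, treatment over control.
#' @param mu0 positive average read count per sample in the control group.
#' @param phi nonnegative dispersion.
#' @param w ratio of geometric-mean normalization factors (treatment over
#'   control).
#' @param alpha significance level; the test rejects when p < alpha
#'   (strict).
#' @param k ratio of treatment to control group size, `n1 = k * n`.
#' @param epsilon total truncation tail mass (default 1e-10).
#' @param rule two-sided p-value rule, see [exact_test_pvalue()].
#' @return power in \[0, 1\].
#' @examples
#' nb_power(n = 4, rho = 4, mu0 = 5, phi = 0.1, alpha = 0.001)
#' @export
nb_power <- function(n, rho, mu0, phi, w = 1, alpha, k = 1,
                     epsilon = 1e-10, rule = c("smallp", "doubletail")) {
  rule <- match.arg(rule)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n))
    stop("'n' must be a single positive integer", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("'rho' must be a single positive number", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("'alpha' must be a single number", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0 ||
      (k * n) != floor(k * n))
    stop("'k' must make n1 = k * n a positive integer", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 || epsilon >= 1)
    stop("'epsilon' must be in (0, 1)", call. = FALSE)
  if (alpha <= 0) return(0)  # p-values are strictly positive

  n0 <- as.integer(n)
  n1 <- as.integer(k * n)
  .check_nb_spec(mu0, phi)

  mu1_null <- n1 * w * mu0
  mu0_null <- n0 * mu0
  mu1_alt <- n1 * w * rho * mu0
  ph1 <- phi / n1
  ph0 <- phi / n0

  B1 <- nb_tail_bound(mu1_alt, ph1, epsilon / 2)
  B0 <- nb_tail_bound(mu0_null, ph0, epsilon / 2)
  S <- B1 + B0
  ys <- 0:S
  l1n <- nb_pmf(ys, mu1_null, ph1, log = TRUE)
  l0n <- nb_pmf(ys, mu0_null, ph0, log = TRUE)
  l1a <- nb_pmf(ys, mu1_alt, ph1, log = TRUE)
  l0a <- nb_pmf(ys, mu0_null, ph0, log = TRUE)

  pow <- 0
  for (s in 0:S) {
    a <- 0:s
    lq <- l1n[a + 1L] + l0n[s - a + 1L]
    z <- .logsumexp(lq)
    if (!is.finite(z)) next  # total unreachable under the null at this scale
    q <- exp(lq - z)
    q <- q / sum(q)
    pv <- .pvalues_from_q(q, rule)
    rej <- pv < alpha & a <= B1 & (s - a) <= B0
    if (any(rej))
      pow <- pow + sum(exp(l1a[a[rej] + 1L] + l0a[s - a[rej] + 1L]))
  }
  min(pow, 1)
}
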