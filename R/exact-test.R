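# NB exact test for one gene. The two group pseudo-sums are modeled as
# Y0 ~ NB(n0 * mu0, phi/n0) and Y1 ~ NB(n1 * w * mu0, phi/n1) under the
# null of equal expression; the test conditions on the total s = Y1 + Y0
# and, in analogy with Fisher's exact test, sums the conditional
# probabilities of all outcomes no more likely than the observed one.

#' Null model for the two group pseudo-sums
#'
#' Bundles the design quantities that determine the null distribution of
#' the per-group sums of (pseudo)counts for one gene: group sizes, the
#' per-sample control mean `mu0`, the ratio `w` of geometric-mean
#' normalization factors (treatment over control), and the per-sample
#' dispersion `phi`. The implied null marginals are
#' `Y0 ~ NB(n0 * mu0, phi/n0)` and `Y1 ~ NB(n1 * w * mu0, phi/n1)`.
#'
#' @param n0,n1 samples in the control and treatment group.
#' @param mu0 positive per-sample mean read count in the control group.
#' @param w positive ratio of geometric-mean normalization factors.
#' @param phi nonnegative per-sample dispersion.
#' @return an object of class `"group_null_model"`.
#' @examples
#' group_null_model(n0 = 3, n1 = 3, mu0 = 5, w = 1, phi = 0.1)
#' @export
group_null_model <- function(n0, n1, mu0, w = 1, phi) {
  for (nm in c("n0", "n1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 || v != floor(v))
      stop(sprintf("'%s' must be a positive integer", nm), call. = FALSE)
  }
  if (!is.numeric(mu0) || length(mu0) != 1L || !is.finite(mu0) || mu0 <= 0)
    stop("'mu0' must be a single positive number", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0)
    stop("'w' must be a single positive number", call. = FALSE)
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi < 0)
    stop("'phi' must be a single nonnegative number", call. = FALSE)
  structure(list(n0 = as.integer(n0), n1 = as.integer(n1),
                 mu0 = mu0, w = w, phi = phi),
            class = "group_null_model")
}

#' @export
print.group_null_model <- function(x, ...) {
  cat("Group null model for NB exact test\n")
  cat(sprintf("  n0 = %d, n1 = %d, mu0 = %g, w = %g, phi = %g\n",
              x$n0, x$n1, x$mu0, x$w, x$phi))
  cat(sprintf("  null marginals: Y0 ~ NB(%g, %g), Y1 ~ NB(%g, %g)\n",
              x$n0 * x$mu0, x$phi / x$n0, x$n1 * x$w * x$mu0, x$phi / x$n1))
  invisible(x)
}

# log joint null probabilities of (Y1 = a, Y0 = s - a), a = 0..s, unnormalized
.cond_logq <- function(s, model) {
  a <- 0:s
  l1 <- nb_pmf(a, model$n1 * model$w * model$mu0, model$phi / model$n1, log = TRUE)
  l0 <- nb_pmf(s - a, model$n0 * model$mu0, model$phi / model$n0, log = TRUE)
  l1 + l0
}

#' Conditional null distribution of the treatment pseudo-sum
#'
#' Distribution of `Y1` given the total `Y1 + Y0 = s` under the null of
#' equal expression: entry `a + 1` is
#' `P(Y1 = a) P(Y0 = s - a) / sum_b P(Y1 = b) P(Y0 = s - b)`.
#' Since `s` is finite the normalization enumerates all `s + 1` outcomes;
#' no truncation is involved. Computed in log space, so jointly tiny
#' probabilities at large totals normalize without underflow.
#'
#' @param s nonnegative integer total of the two group sums.
#' @param model a [group_null_model()].
#' @return probability vector of length `s + 1`, summing to 1.
#' @examples
#' m <- group_null_model(2, 2, mu0 = 1, w = 1, phi = 0.5)
#' conditional_null_distribution(4, m)  # symmetric around 2
#' @export
conditional_null_distribution <- function(s, model) {
  stopifnot(inherits(model, "group_null_model"))
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s < 0 || s != floor(s))
    stop("'s' must be a single nonnegative integer", call. = FALSE)
  lq <- .cond_logq(s, model)
  z <- .logsumexp(lq)
  if (!is.finite(z))
    stop("all joint null probabilities underflowed; total too extreme for model",
         call. = FALSE)
  q <- exp(lq - z)
  q / sum(q)
}

# two-sided p-values for every a = 0..s given conditional probabilities q.
# smallp: sum of probabilities of outcomes no more likely than a (with a
# relative tie tolerance so analytically tied outcomes are not dropped);
# doubletail: twice the smaller tail, capped at 1.
.pvalues_from_q <- function(q, rule = c("smallp", "doubletail"), tie_tol = 1e-7) {
  rule <- match.arg(rule)
  if (rule == "smallp") {
    ord <- order(q)
    cs <- cumsum(q[ord])
    idx <- findInterval(q * (1 + tie_tol), q[ord])
    pmin(cs[pmax(idx, 1L)], 1)
  } else {
    lo <- cumsum(q)
    hi <- rev(cumsum(rev(q)))
    pmin(2 * pmin(lo, hi), 1)
  }
}

#' Exact test p-value for one gene
#'
#' Two-sided p-value of the NB exact test given the observed treatment and
#' control pseudo-sums. The default `"smallp"` rule sums the conditional
#' null probabilities of all outcomes whose probability does not exceed that
#' of the observed one (up to a relative tie tolerance); the `"doubletail"`
#' rule doubles the smaller conditional tail and caps at 1, and is exposed
#' for sensitivity checks against implementations that default to it.
#'
#' @param y1,y0 observed treatment and control pseudo-sums (nonnegative
#'   integers).
#' @param model a [group_null_model()].
#' @param rule two-sided rule, `"smallp"` (default) or `"doubletail"`.
#' @param tie_tol relative tolerance when comparing conditional
#'   probabilities for the `"smallp"` rule.
#' @return p-value in (0, 1].
#' @examples
#' m <- group_null_model(3, 3, mu0 = 1, w = 1, phi = 0.2)
#' exact_test_pvalue(10, 0, m)
#' @export
exact_test_pvalue <- function(y1, y0, model, rule = c("smallp", "doubletail"),
                              tie_tol = 1e-7) {
  stopifnot(inherits(model, "group_null_model"))
  rule <- match.arg(rule)
  for (nm in c("y1", "y0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v != floor(v))
      stop(sprintf("'%s' must be a single nonnegative integer", nm), call. = FALSE)
  }
  s <- y1 + y0
  if (s == 0) return(1)
  q <- conditional_null_distribution(s, model)
  .pvalues_from_q(q, rule, tie_tol)[y1 + 1L]
}

# vectorized p-values for many genes sharing (n0, n1, w, phi): genes are
# grouped by total s, the conditional distribution is built once per unique
# total with mu0 estimated from that total as s / (n0 + n1 w), and p-values
# are read off for each gene's y1. Genes with s = 0 are untestable (p = 1).
.pvalues_group_sums <- function(s1, s0, n1, n0, w, phi,
                                rule = "smallp", tie_tol = 1e-7) {
  s <- s1 + s0
  p <- rep(1, length(s))
  for (sv in unique(s)) {
    if (sv == 0) next
    idx <- which(s == sv)
    mu0 <- sv / (n0 + n1 * w)
    model <- group_null_model(n0, n1, mu0 = mu0, w = w, phi = phi)
    q <- conditional_null_distribution(sv, model)
    pa <- .pvalues_from_q(q, rule, tie_tol)
    p[idx] <- pa[s1[idx] + 1L]
  }
  p
}
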