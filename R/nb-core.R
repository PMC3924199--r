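#' nbseqpower: power and sample size for the NB exact test
#'
#' Design calculations for two-group RNA-seq differential expression based
#' on the negative binomial exact test: exact power, minimal sample size at
#' a fixed significance level, FDR-controlled multi-gene designs, pilot-data
#' parameter estimation, and a Monte Carlo validation harness.
#'
#' @keywords internal
"_PACKAGE"

# mean/dispersion parameterization used throughout: Y ~ NB(mu, phi) has
# E(Y) = mu and Var(Y) = mu * (1 + mu * phi); phi = 0 is the Poisson limit.
# The (size, prob) form used by R is size = 1/phi; conversion happens only
# at the dnbinom/qnbinom call sites.

.check_nb_spec <- function(mean, dispersion) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("'mean' must be a single positive number", call. = FALSE)
  if (!is.numeric(dispersion) || length(dispersion) != 1L ||
      !is.finite(dispersion) || dispersion < 0)
    stop("'dispersion' must be a single nonnegative number", call. = FALSE)
  invisible(TRUE)
}

#' Negative binomial probability mass in mean/dispersion form
#'
#' Probability of observing `y` reads under NB(`mean`, `dispersion`) with
#' variance `mean * (1 + mean * dispersion)`. `dispersion = 0` is handled as
#' an explicit Poisson branch rather than a large-size approximation, so
#' near-Poisson designs (e.g. dispersions of order 1e-3 estimated from
#' technical replicates) are numerically stable. Evaluation is in log space
#' throughout; counts up to at least 1e6 do not overflow.
#'
#' @param y vector of nonnegative integer counts.
#' @param mean positive expected read count.
#' @param dispersion nonnegative dispersion (0 = Poisson).
#' @param log return log-probabilities?
#' @return numeric vector of (log-)probabilities, one per element of `y`.
#' @examples
#' nb_pmf(0, mean = 1, dispersion = 1)   # 0.5
#' nb_pmf(0, mean = 2, dispersion = 0)   # exp(-2)
#' @export
nb_pmf <- function(y, mean, dispersion, log = FALSE) {
  .check_nb_spec(mean, dispersion)
  if (length(y) == 0L) return(numeric(0))
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y)))
    stop("'y' must contain nonnegative integers", call. = FALSE)
  lp <- if (dispersion == 0)
    stats::dpois(y, lambda = mean, log = TRUE)
  else
    stats::dnbinom(y, mu = mean, size = 1 / dispersion, log = TRUE)
  if (log) lp else exp(lp)
}

#' Upper tail truncation bound
#'
#' Smallest integer `B` such that `P(Y > B) <= epsilon` for
#' Y ~ NB(`mean`, `dispersion`). Used to truncate the infinite sums in the
#' power function with a certified tail mass.
#'
#' @inheritParams nb_pmf
#' @param epsilon tail mass to leave beyond the bound, in (0, 1).
#' @return nonnegative integer bound.
#' @examples
#' nb_tail_bound(1, 0, 0.5)    # 1: P(Pois(1) > 1) ~ 0.264
#' @export
nb_tail_bound <- function(mean, dispersion, epsilon) {
  .check_nb_spec(mean, dispersion)
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      !is.finite(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("'epsilon' must be in (0, 1)", call. = FALSE)
  # q*(1 - eps) is the smallest x with F(x) >= 1 - eps, which is exactly
  # the smallest B with P(Y > B) <= eps
  if (dispersion == 0)
    stats::qpois(1 - epsilon, lambda = mean)
  else
    stats::qnbinom(1 - epsilon, mu = mean, size = 1 / dispersion)
}

# log(sum(exp(x))) without overflow; x may contain -Inf
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
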