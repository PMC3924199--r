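# Sample-size solving: single-gene designs at a fixed level, and
# FDR-controlled multi-gene designs via the identity f = m0 a / (m0 a + r1)
# linking the per-test level to the target number of true rejections.

#' Marginal type I error level implied by an FDR target
#'
#' Solves `f = m0 * alpha / (m0 * alpha + r1)` for `alpha`: the per-test
#' significance level at which `r1` expected true rejections among `m0`
#' true nulls control the FDR at level `f`.
#'
#' @param r1 target number of true rejections (nonnegative).
#' @param f FDR level in (0, 1).
#' @param m0 number of true null genes (>= 1).
#' @return the level `r1 * f / (m0 * (1 - f))`.
#' @examples
#' fdr_alpha_star(80, 0.01, 9900)    # 8.162e-05
#' fdr_alpha_star(140, 0.01, 17131)  # 8.2549e-05
#' @export
fdr_alpha_star <- function(r1, f, m0) {
  if (!is.numeric(r1) || length(r1) != 1L || !is.finite(r1) || r1 < 0)
    stop("'r1' must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0 || f >= 1)
    stop("'f' must be in (0, 1)", call. = FALSE)
  if (!is.numeric(m0) || length(m0) != 1L || !is.finite(m0) || m0 < 1)
    stop("'m0' must be >= 1", call. = FALSE)
  r1 * f / (m0 * (1 - f))
}

#' Type II error rate implied by a target number of true rejections
#'
#' `beta* = 1 - r1/m1`: the marginal type II error rate when `r1` of the
#' `m1` prognostic genes are to be detected.
#'
#' @param r1 target number of true rejections, `0 < r1 <= m1`.
#' @param m1 number of prognostic genes.
#' @return `1 - r1 / m1`.
#' @examples
#' fdr_beta_star(140, 175)  # 0.2
#' @export
fdr_beta_star <- function(r1, m1) {
  if (!is.numeric(r1) || length(r1) != 1L || !is.finite(r1) || r1 <= 0)
    stop("'r1' must be a single positive number", call. = FALSE)
  if (!is.numeric(m1) || length(m1) != 1L || !is.finite(m1) || m1 < r1)
    stop("'m1' must be >= r1", call. = FALSE)
  1 - r1 / m1
}

#' Conservative least-favourable design parameters
#'
#' Reduces per-gene design parameters to the single least-favourable triple:
#' the fold change with the smallest `|log2(rho)|`, the minimum control-group
#' mean and the maximum dispersion. Power increases in `|log2(rho)|` and
#' `mu0` and decreases in `phi`, so a design sized at this triple is an
#' upper bound for the per-gene design. A tie in `|log2(rho)|` is broken
#' toward the candidate below 1, for determinism.
#'
#' @param rho,mu0,phi equal-length vectors of per-gene fold changes,
#'   control means and dispersions.
#' @return named numeric vector `c(rho, mu0, phi)`.
#' @examples
#' conservative_triple(c(2, 8), c(5, 1), c(0.1, 0.5))  # 2, 1, 0.5
#' @export
conservative_triple <- function(rho, mu0, phi) {
  if (length(rho) == 0L) stop("empty parameter list", call. = FALSE)
  if (length(mu0) != length(rho) || length(phi) != length(rho))
    stop("'rho', 'mu0' and 'phi' must have equal length", call. = FALSE)
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("all fold changes must be positive", call. = FALSE)
  al <- abs(log2(rho))
  cand <- which(al == min(al))
  if (length(cand) > 1L) {
    below <- cand[rho[cand] < 1]
    cand <- if (length(below)) below[1L] else cand[1L]
  }
  c(rho = rho[cand], mu0 = min(mu0), phi = max(phi))
}

# smallest integer n >= 2 with powfun(n) >= target: doubling bracket then
# bisection, then a linear certificate that powfun(n - 1) < target. Power is
# empirically monotone in n over design grids but not provably so; the final
# verification is what the returned n is trusted on.
.solve_min_n <- function(powfun, target, n_max) {
  lo <- 2L
  p_lo <- powfun(lo)
  if (p_lo >= target)
    return(list(n = lo, power = p_lo, power_below = NA_real_))
  hi <- 4L
  repeat {
    if (hi > n_max) {
      p_cap <- powfun(as.integer(n_max))
      if (p_cap >= target) { hi <- as.integer(n_max); p_hi <- p_cap; break }
      cond <- structure(
        class = c("nbss_unachievable", "error", "condition"),
        list(message = sprintf(
               "target power %.4g not achievable by n_max = %d (power there: %.4g)",
               target, as.integer(n_max), p_cap),
             call = NULL, power_at_n_max = p_cap, n_max = as.integer(n_max)))
      stop(cond)
    }
    p_hi <- powfun(hi)
    if (p_hi >= target) break
    lo <- hi
    hi <- 2L * hi
  }
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (powfun(mid) >= target) { hi <- mid; p_hi <- powfun(mid) } else lo <- mid
  }
  p_below <- powfun(hi - 1L)
  if (p_below >= target)  # bisection landed above the first crossing
    return(.solve_min_n_linear(powfun, target, hi - 1L))
  list(n = hi, power = p_hi, power_below = p_below)
}

# walk down until the minimality certificate holds
.solve_min_n_linear <- function(powfun, target, n_start) {
  n <- n_start
  repeat {
    if (n == 2L) return(list(n = 2L, power = powfun(2L), power_below = NA_real_))
    p_below <- powfun(n - 1L)
    if (p_below < target)
      return(list(n = n, power = powfun(n), power_below = p_below))
    n <- n - 1L
  }
}

#' Minimal sample size for a single-gene comparison
#'
#' Smallest per-group sample size `n >= 2` at which the exact test attains
#' the target power at significance level `alpha`, found by bracketing and
#' bisection on the integer power curve with a final minimality certificate
#' (`power(n) >= target`, `power(n - 1) < target`). An explicit error of
#' class `"nbss_unachievable"` carrying the power at `n_max` is raised when
#' the target cannot be met.
#'
#' @inheritParams nb_power
#' @param power target power `1 - beta`, in (0, 1).
#' @param n_max search cap on the per-group sample size.
#' @return an object of class `"nbss"`: a list with the minimal `n`, the
#'   achieved power at `n` and at `n - 1`, and all inputs echoed.
#' @examples
#' nb_sample_size(rho = 4, mu0 = 5, phi = 0.1, alpha = 0.001, power = 0.8)
#' @seealso [nb_sample_size_fdr()] for FDR-controlled multi-gene designs.
#' @export
nb_sample_size <- function(rho, mu0, phi, w = 1, alpha, power = 0.8, k = 1,
                           n_max = 10000, epsilon = 1e-10,
                           rule = c("smallp", "doubletail")) {
  rule <- match.arg(rule)
  if (!is.numeric(power) || length(power) != 1L || power <= 0 || power >= 1)
    stop("'power' must be in (0, 1)", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  powfun <- function(n) nb_power(n, rho = rho, mu0 = mu0, phi = phi, w = w,
                                 alpha = alpha, k = k, epsilon = epsilon,
                                 rule = rule)
  sol <- .solve_min_n(powfun, power, n_max)
  structure(list(n = sol$n, power = sol$power, power_below = sol$power_below,
                 target_power = power, rho = rho, mu0 = mu0, phi = phi,
                 w = w, alpha = alpha, k = k, epsilon = epsilon, rule = rule,
                 n_max = as.integer(n_max)),
            class = "nbss")
}

#' Sample size controlling the false discovery rate
#'
#' Sizes a multi-gene two-group RNA-seq experiment so that `r1` true
#' rejections among `m1` prognostic genes are expected while the FDR is
#' controlled at level `f`. The per-test level is
#' `alpha* = r1 f / (m0 (1 - f))` with `m0 = m - m1`. In conservative mode
#' (scalar `rho`, `mu0`, `phi`) the single-gene solver is run at `alpha*`
#' with target power `r1/m1`. In per-gene mode (`per_gene` a data frame with
#' columns `rho`, `mu0`, `phi`) the solver finds the smallest `n` with
#' `sum_g xi(n, rho_g, mu0_g, phi_g, w, alpha*) >= r1`.
#'
#' @param m total number of genes tested.
#' @param m1 number of prognostic (truly differentially expressed) genes.
#' @param r1 target number of true rejections, `0 < r1 <= m1`.
#' @param f FDR level in (0, 1).
#' @param rho,mu0,phi conservative design parameters (ignored when
#'   `per_gene` is given).
#' @param per_gene optional data frame of per-gene `rho`, `mu0`, `phi`.
#' @inheritParams nb_sample_size
#' @return an object of class `c("nbss_fdr", "nbss")` with the minimal `n`,
#'   `alpha_star`, `beta_star`, achieved (summed) power at `n` and `n - 1`,
#'   and all inputs echoed.
#' @examples
#' \donttest{
#' nb_sample_size_fdr(m = 1000, m1 = 10, r1 = 8, f = 0.05,
#'                    rho = 4, mu0 = 5, phi = 0.1)
#' }
#' @export
nb_sample_size_fdr <- function(m, m1, r1, f, rho = NULL, mu0 = NULL,
                               phi = NULL, w = 1, per_gene = NULL, k = 1,
                               n_max = 10000, epsilon = 1e-10,
                               rule = c("smallp", "doubletail")) {
  rule <- match.arg(rule)
  for (nm in c("m", "m1", "r1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  if (m1 >= m) stop("'m1' must be smaller than 'm'", call. = FALSE)
  if (r1 > m1) stop("'r1' cannot exceed 'm1'", call. = FALSE)
  m0 <- m - m1
  alpha_star <- fdr_alpha_star(r1, f, m0)
  beta_star <- fdr_beta_star(r1, m1)
  if (alpha_star >= 1)
    stop("implied alpha* >= 1; lower r1 or f", call. = FALSE)

  if (is.null(per_gene)) {
    if (is.null(rho) || is.null(mu0) || is.null(phi))
      stop("either conservative 'rho', 'mu0', 'phi' or 'per_gene' required",
           call. = FALSE)
    base <- nb_sample_size(rho = rho, mu0 = mu0, phi = phi, w = w,
                           alpha = alpha_star, power = r1 / m1, k = k,
                           n_max = n_max, epsilon = epsilon, rule = rule)
    out <- unclass(base)
    out$mode <- "conservative"
  } else {
    if (!is.data.frame(per_gene) ||
        !all(c("rho", "mu0", "phi") %in% names(per_gene)))
      stop("'per_gene' must be a data frame with columns rho, mu0, phi",
           call. = FALSE)
    if (nrow(per_gene) == 0L) stop("'per_gene' is empty", call. = FALSE)
    sumpow <- function(n) {
      sum(vapply(seq_len(nrow(per_gene)), function(g)
        nb_power(n, rho = per_gene$rho[g], mu0 = per_gene$mu0[g],
                 phi = per_gene$phi[g], w = w, alpha = alpha_star, k = k,
                 epsilon = epsilon, rule = rule), numeric(1)))
    }
    sol <- .solve_min_n(sumpow, r1, n_max)
    out <- list(n = sol$n, power = sol$power / nrow(per_gene),
                power_below = if (is.na(sol$power_below)) NA_real_
                              else sol$power_below / nrow(per_gene),
                target_power = r1 / m1, rho = NA_real_, mu0 = NA_real_,
                phi = NA_real_, w = w, alpha = alpha_star, k = k,
                epsilon = epsilon, rule = rule, n_max = as.integer(n_max),
                mode = "per_gene", per_gene = per_gene)
  }
  out$m <- m; out$m1 <- m1; out$m0 <- m0; out$r1 <- r1; out$f <- f
  out$alpha_star <- alpha_star; out$beta_star <- beta_star
  class(out) <- c("nbss_fdr", "nbss")
  out
}

#' @export
print.nbss <- function(x, ...) {
  cat("Sample size for the NB exact test\n\n")
  if (inherits(x, "nbss_fdr")) {
    cat(sprintf("  genes m = %g (prognostic m1 = %g), true rejections r1 = %g, FDR f = %g\n",
                x$m, x$m1, x$r1, x$f))
    cat(sprintf("  alpha* = %.6g, beta* = %.4g, mode = %s\n",
                x$alpha_star, x$beta_star, x$mode))
  }
  if (!inherits(x, "nbss_fdr") || x$mode == "conservative")
    cat(sprintf("  rho = %g, mu0 = %g, phi = %g, w = %g, alpha = %.6g\n",
                x$rho, x$mu0, x$phi, x$w, x$alpha))
  else
    cat(sprintf("  %d per-gene parameter sets, w = %g, alpha = %.6g\n",
                nrow(x$per_gene), x$w, x$alpha))
  cat(sprintf("\n  n = %d per group%s\n", x$n,
              if (x$k != 1) sprintf(" (control; treatment n1 = %d)",
                                    as.integer(x$k * x$n)) else ""))
  cat(sprintf("  achieved power %.4f at n, %s at n - 1 (target %.4f)\n",
              x$power,
              if (is.na(x$power_below)) "--" else sprintf("%.4f", x$power_below),
              x$target_power))
  invisible(x)
}

#' @export
summary.nbss <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' Power curve around a solved design
#'
#' Plots exact power against per-group sample size in a window around the
#' solved `n`, with the target power marked.
#'
#' @param x an `"nbss"` object.
#' @param span integer half-width of the window around the solved `n`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a data frame of (n, power) pairs.
#' @export
plot.nbss <- function(x, span = 5L, ...) {
  ns <- seq.int(max(2L, x$n - span), x$n + span)
  if (inherits(x, "nbss_fdr") && x$mode == "per_gene") {
    pw <- vapply(ns, function(n) mean(vapply(seq_len(nrow(x$per_gene)),
      function(g) nb_power(n, x$per_gene$rho[g], x$per_gene$mu0[g],
                           x$per_gene$phi[g], w = x$w, alpha = x$alpha,
                           k = x$k, epsilon = x$epsilon, rule = x$rule),
      numeric(1))), numeric(1))
  } else {
    pw <- vapply(ns, function(n) nb_power(n, x$rho, x$mu0, x$phi, w = x$w,
                                          alpha = x$alpha, k = x$k,
                                          epsilon = x$epsilon, rule = x$rule),
                 numeric(1))
  }
  graphics::plot(ns, pw, type = "b", xlab = "n per group", ylab = "power", ...)
  graphics::abline(h = x$target_power, lty = 2)
  graphics::abline(v = x$n, lty = 3)
  invisible(data.frame(n = ns, power = pw))
}
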