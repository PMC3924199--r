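# Monte Carlo validation harness: simulate full count matrices under a
# design, test every gene with the exact test, control FDR with Storey
# q-values, and report the achieved number of true rejections.

#' Specify a simulation design
#'
#' Conditions for the validation experiment: `m` independent NB genes of
#' which the first `m1` are prognostic. Control samples draw from
#' NB(`mu0`, `phi`); treatment samples draw from NB(`w * rho * mu0`, `phi`)
#' for prognostic genes and NB(`w * mu0`, `phi`) for null genes (`w` scales
#' every treatment mean, emulating a depth imbalance; `w = 1` gives equal
#' null means in both groups).
#'
#' @param m total number of genes.
#' @param m1 number of prognostic genes, `m1 <= m`.
#' @param n per-group sample size.
#' @param mu0 control-group mean read count.
#' @param rho fold change of the prognostic genes.
#' @param phi dispersion (0 = Poisson).
#' @param w normalization-factor ratio applied to treatment means.
#' @param f FDR level for q-value rejection.
#' @param reps number of Monte Carlo replicates.
#' @param seed base RNG seed; each replicate derives its own stream from
#'   `(seed, replicate)`.
#' @return an object of class `"simulation_design"`.
#' @export
simulation_design <- function(m, m1, n, mu0, rho, phi, w = 1, f = 0.05,
                              reps = 1, seed = 1) {
  for (nm in c("m", "m1", "n", "reps", "seed")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v != floor(v))
      stop(sprintf("'%s' must be a single integer", nm), call. = FALSE)
  }
  if (m < 1 || m1 < 0 || m1 > m) stop("need 0 <= m1 <= m", call. = FALSE)
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  .check_nb_spec(mu0, phi)
  if (!is.numeric(rho) || rho <= 0) stop("'rho' must be positive", call. = FALSE)
  if (!is.numeric(w) || w <= 0) stop("'w' must be positive", call. = FALSE)
  if (!is.numeric(f) || f <= 0 || f >= 1) stop("'f' must be in (0, 1)", call. = FALSE)
  structure(list(m = as.integer(m), m1 = as.integer(m1), n = as.integer(n),
                 mu0 = mu0, rho = rho, phi = phi, w = w, f = f,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(
    "Simulation design: m = %d (m1 = %d prognostic), n = %d/group\n",
    x$m, x$m1, x$n))
  cat(sprintf("  mu0 = %g, rho = %g, phi = %g, w = %g, FDR f = %g\n",
              x$mu0, x$rho, x$phi, x$w, x$f))
  cat(sprintf("  %d replicate(s), seed %d\n", x$reps, x$seed))
  invisible(x)
}

# deterministic per-replicate stream key; stays inside 32-bit integer range
.replicate_seed <- function(seed, replicate) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(replicate)) %% 2147483629)
}

# NB draws honouring the phi = 0 Poisson limit
.rnb <- function(k, mu, phi) {
  if (phi == 0) stats::rpois(k, mu) else stats::rnbinom(k, mu = mu, size = 1 / phi)
}

#' Simulate one replicate count matrix
#'
#' Generates the genes-by-samples matrix of a [simulation_design()]
#' replicate: control columns first, then treatment columns; the first `m1`
#' genes are prognostic. Deterministic given `(design$seed, replicate)`.
#'
#' @param design a [simulation_design()].
#' @param replicate replicate index (>= 1).
#' @return list with `counts` (m x 2n integer matrix), `group` (two-level
#'   factor, control first) and `prognostic` (logical vector of truth
#'   labels).
#' @export
simulate_counts <- function(design, replicate = 1) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(.replicate_seed(design$seed, replicate))
  m <- design$m; m1 <- design$m1; n <- design$n
  y0 <- matrix(.rnb(m * n, design$mu0, design$phi), m, n)
  y1 <- matrix(.rnb(m * n, design$w * design$mu0, design$phi), m, n)
  if (m1 > 0)
    y1[seq_len(m1), ] <- .rnb(m1 * n, design$w * design$rho * design$mu0,
                              design$phi)
  counts <- cbind(y0, y1)
  dimnames(counts) <- list(sprintf("gene%05d", seq_len(m)),
                           c(sprintf("ctrl%02d", seq_len(n)),
                             sprintf("trt%02d", seq_len(n))))
  list(counts = counts,
       group = factor(rep(c("control", "treatment"), each = n),
                      levels = c("control", "treatment")),
       prognostic = seq_len(m) <= m1)
}

#' Storey q-values
#'
#' Computes `pi0-hat = #\{p > lambda\} / (m (1 - lambda))`, capped at 1 and
#' floored at `1/m`, and `q_i = min over p_j >= p_i of pi0-hat m p_j /
#' rank(p_j)`. Rejecting at `q <= f` controls the FDR at level `f` for
#' independent or weakly dependent tests.
#'
#' @param p vector of p-values in (0, 1].
#' @param lambda tuning parameter in \[0, 1) for the null-proportion
#'   estimate.
#' @return q-value vector in \[0, 1\], monotone in `p`.
#' @examples
#' qvalues(c(0.001, 0.02, 0.5, 1, 1))
#' @export
qvalues <- function(p, lambda = 0.5) {
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda >= 1)
    stop("'lambda' must be in [0, 1)", call. = FALSE)
  m <- length(p)
  pi0 <- sum(p > lambda) / (m * (1 - lambda))
  pi0 <- min(1, max(1 / m, pi0))  # floor avoids zero rejections by fiat
  o <- order(p)
  q <- pmin(pi0 * m * p[o] / seq_len(m), 1)
  q <- rev(cummin(rev(q)))  # enforce monotonicity in p
  out <- numeric(m)
  out[o] <- q
  out
}

#' Run the Monte Carlo validation experiment
#'
#' For each replicate: simulate counts, estimate per-sample normalization
#' factors and the group ratio `w`, estimate a pooled common dispersion
#' from the conditional likelihood, compute per-gene exact-test p-values on
#' the group sums, reject at Storey q-value `<= f`, and count true and
#' false rejections. Genes with zero total count are untestable and get
#' p = 1.
#'
#' @param design a [simulation_design()].
#' @param rule two-sided p-value rule, see [exact_test_pvalue()].
#' @param norm_method normalization for the per-replicate analysis,
#'   see [norm_factors()].
#' @param dispersion `"pooled"` estimates the common dispersion per
#'   replicate; `"true"` plugs in the generating `phi` (useful to separate
#'   estimation error from test behaviour).
#' @param lambda q-value tuning parameter.
#' @param verbose print a line every 100 replicates.
#' @return an object of class `"nbss_sim"`: per-replicate rejection counts
#'   (`replicates`: replicate, R, R0, R1), the mean true rejections
#'   `r1_hat` with Monte Carlo standard error `se`, the empirical FDR, and
#'   the design.
#' @export
run_validation <- function(design, rule = c("smallp", "doubletail"),
                           norm_method = c("TMM", "libsize"),
                           dispersion = c("pooled", "true"), lambda = 0.5,
                           verbose = FALSE) {
  stopifnot(inherits(design, "simulation_design"))
  rule <- match.arg(rule)
  norm_method <- match.arg(norm_method)
  dispersion <- match.arg(dispersion)
  n <- design$n
  out <- matrix(0L, design$reps, 3L,
                dimnames = list(NULL, c("R", "R0", "R1")))
  phis <- ws <- numeric(design$reps)
  for (r in seq_len(design$reps)) {
    sim <- simulate_counts(design, r)
    ctrl <- sim$group == "control"
    d <- norm_factors(sim$counts, method = norm_method)
    w_hat <- ratio_w(d, sim$group)
    phi_hat <- if (dispersion == "pooled")
      pooled_dispersion(sim$counts, sim$group) else design$phi
    s1 <- rowSums(sim$counts[, !ctrl, drop = FALSE])
    s0 <- rowSums(sim$counts[, ctrl, drop = FALSE])
    p <- .pvalues_group_sums(s1, s0, n, n, w_hat, phi_hat, rule = rule)
    q <- qvalues(p, lambda = lambda)
    rej <- q <= design$f
    R1 <- sum(rej & sim$prognostic)
    R0 <- sum(rej & !sim$prognostic)
    out[r, ] <- c(R1 + R0, R0, R1)
    phis[r] <- phi_hat; ws[r] <- w_hat
    if (verbose && r %% 100L == 0L)
      message(sprintf("replicate %d/%d: R1 = %d, R0 = %d", r, design$reps,
                      R1, R0))
  }
  reps_df <- data.frame(replicate = seq_len(design$reps), out)
  with_rej <- reps_df$R > 0
  structure(list(
    replicates = reps_df,
    r1_hat = mean(reps_df$R1),
    se = stats::sd(reps_df$R1) / sqrt(design$reps),
    empirical_fdr = if (any(with_rej))
      mean(reps_df$R0[with_rej] / reps_df$R[with_rej]) else NA_real_,
    phi_hat = mean(phis), w_hat = mean(ws),
    design = design, rule = rule, norm_method = norm_method,
    dispersion = dispersion, lambda = lambda),
    class = "nbss_sim")
}

#' @export
print.nbss_sim <- function(x, ...) {
  print(x$design)
  cat(sprintf("\n  mean true rejections r1_hat = %.2f (MC se %.3f)\n",
              x$r1_hat, x$se))
  cat(sprintf("  empirical FDR = %s (nominal f = %g)\n",
              if (is.na(x$empirical_fdr)) "--" else
                sprintf("%.4f", x$empirical_fdr), x$design$f))
  cat(sprintf("  mean pooled dispersion %.4g, mean w-hat %.4g\n",
              x$phi_hat, x$w_hat))
  invisible(x)
}

#' Simulate count matrices under a solved FDR design
#'
#' Draws replicate count matrices at the solved per-group sample size using
#' the design's conservative parameters; a convenience bridge from
#' [nb_sample_size_fdr()] to [simulate_counts()].
#'
#' @param object an `"nbss_fdr"` object solved in conservative mode.
#' @param nsim number of replicate matrices.
#' @param seed base RNG seed.
#' @param ... unused.
#' @return list of `nsim` results of [simulate_counts()].
#' @export
simulate.nbss_fdr <- function(object, nsim = 1, seed = 1, ...) {
  if (!identical(object$mode, "conservative"))
    stop("simulate() requires a conservative-mode design", call. = FALSE)
  des <- simulation_design(m = object$m, m1 = object$m1, n = object$n,
                           mu0 = object$mu0, rho = object$rho,
                           phi = object$phi, w = object$w, f = object$f,
                           reps = nsim, seed = seed)
  lapply(seq_len(nsim), function(r) simulate_counts(des, r))
}
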