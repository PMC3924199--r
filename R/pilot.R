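# Pilot-data estimation of design inputs: per-sample normalization factors,
# the group ratio w, per-gene (mu0, rho, phi) and exact-test p-values, and
# the prognostic gene set used to form the conservative design triple.

# normalize a 2-level group labelling; first level is the control group
.as_group <- function(group, n_samples) {
  g <- as.factor(group)
  if (length(g) != n_samples)
    stop("'group' must have one label per sample", call. = FALSE)
  if (nlevels(g) != 2L)
    stop("'group' must have exactly two levels (control first)", call. = FALSE)
  droplevels(g)
}

#' Read a gene-by-sample count matrix
#'
#' Reads tab- or comma-separated text with a header row of sample names and
#' a first column of gene identifiers. Duplicate gene identifiers and
#' negative or non-integer entries are rejected.
#'
#' @param file path to the counts file.
#' @param sep field separator; `NULL` (default) picks tab when the first
#'   line contains tabs, comma otherwise.
#' @return integer matrix, genes in rows (named), samples in columns.
#' @export
read_count_matrix <- function(file, sep = NULL) {
  if (is.null(sep)) {
    l1 <- readLines(file, n = 1L)
    sep <- if (grepl("\t", l1)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in counts file", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m)))
    stop("counts must be nonnegative integers", call. = FALSE)
  rownames(m) <- ids
  m
}

#' Filter genes with too few reads in either group
#'
#' Keeps genes whose total read count exceeds `min_total` in both groups
#' separately; a gene scarce in either group is dropped. The default of 5
#' mirrors the usual "no more than 5 total reads" pilot filter.
#'
#' @param counts genes-by-samples count matrix.
#' @param group two-level sample labelling, control level first.
#' @param min_total threshold; genes must exceed it in each group.
#' @return the filtered count matrix.
#' @export
filter_low_count_genes <- function(counts, group, min_total = 5) {
  g <- .as_group(group, ncol(counts))
  if (min_total < 0) stop("'min_total' must be >= 0", call. = FALSE)
  t0 <- rowSums(counts[, g == levels(g)[1L], drop = FALSE])
  t1 <- rowSums(counts[, g == levels(g)[2L], drop = FALSE])
  keep <- t0 > min_total & t1 > min_total
  if (!any(keep))
    stop("no genes left after low-count filtering", call. = FALSE)
  counts[keep, , drop = FALSE]
}

#' Per-sample normalization factors
#'
#' Effective scaling factor `d_j` for each sample, normalized so the
#' factors have geometric mean 1. `"TMM"` (default) computes trimmed mean
#' of M-values factors (30% M trim, 5% A trim, reference sample with upper
#' quartile closest to the mean upper quartile) and multiplies them by
#' library size; `"libsize"` uses library size alone.
#'
#' @param counts genes-by-samples count matrix.
#' @param method `"TMM"` or `"libsize"`.
#' @return numeric vector of positive per-sample factors, geometric mean 1.
#' @export
norm_factors <- function(counts, method = c("TMM", "libsize")) {
  method <- match.arg(method)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with all-zero counts", call. = FALSE)
  d <- if (method == "TMM")
    lib * edgeR::calcNormFactors(as.matrix(counts), method = "TMM")
  else lib
  d <- d / exp(mean(log(d)))
  names(d) <- colnames(counts)
  d
}

#' Ratio of geometric-mean normalization factors
#'
#' `w = d1* / d0*`: geometric mean of the treatment-group factors over the
#' geometric mean of the control-group factors.
#'
#' @param factors per-sample normalization factors.
#' @param group two-level sample labelling, control level first.
#' @return positive scalar `w`.
#' @export
ratio_w <- function(factors, group) {
  g <- .as_group(group, length(factors))
  gm <- function(x) exp(mean(log(x)))
  gm(factors[g == levels(g)[2L]]) / gm(factors[g == levels(g)[1L]])
}

#' Pooled common dispersion across genes
#'
#' Single dispersion estimate maximizing the summed per-gene conditional
#' log-likelihoods: within each group the likelihood of the counts given
#' their group total, which does not involve the group means. Assumes
#' approximately equal effective depths within a group (the setting in
#' which the group totals are sufficient for the means).
#'
#' @param counts genes-by-samples count matrix.
#' @param group two-level sample labelling, control level first.
#' @param interval search interval for the dispersion.
#' @return nonnegative dispersion estimate (0 when the optimum sits at the
#'   lower boundary).
#' @export
pooled_dispersion <- function(counts, group, interval = c(1e-6, 20)) {
  g <- .as_group(group, ncol(counts))
  y0 <- counts[, g == levels(g)[1L], drop = FALSE]
  y1 <- counts[, g == levels(g)[2L], drop = FALSE]
  if (ncol(y0) < 2L || ncol(y1) < 2L)
    stop("need >= 2 samples per group for dispersion estimation", call. = FALSE)
  m <- nrow(counts)
  n0 <- ncol(y0); n1 <- ncol(y1)
  # the phi-dependent part of the conditional log-likelihood only touches
  # lgamma(y + r), lgamma(s_i + n_i r), lgamma(r), lgamma(n_i r); tabulating
  # the distinct count and total values collapses the m*(n0+n1) terms
  ty <- table(c(y0, y1))
  yv <- as.numeric(names(ty)); yc <- as.numeric(ty)
  ts0 <- table(rowSums(y0)); ts1 <- table(rowSums(y1))
  s0v <- as.numeric(names(ts0)); s0c <- as.numeric(ts0)
  s1v <- as.numeric(names(ts1)); s1c <- as.numeric(ts1)
  negll <- function(lphi) {
    r <- exp(-lphi)
    -(sum(yc * lgamma(yv + r)) - (n0 + n1) * m * lgamma(r) +
        m * (lgamma(n0 * r) + lgamma(n1 * r)) -
        sum(s0c * lgamma(s0v + n0 * r)) - sum(s1c * lgamma(s1v + n1 * r)))
  }
  opt <- stats::optimize(negll, log(interval), tol = 1e-4)
  phi <- exp(opt$minimum)
  # boundary: optimum indistinguishable from the Poisson limit
  if (phi <= interval[1L] * 1.5 && negll(log(interval[1L])) <= opt$objective + 1e-8)
    phi <- 0
  phi
}

# per-gene NB profile likelihood in phi; group means d_j * gamma_i with
# gamma_i re-maximized at each phi (closed form mean(y)/d when factors are
# equal within the group, 1-d search otherwise)
.phi_mle_gene <- function(y, d, g, interval = c(1e-8, 50)) {
  lev <- levels(g)
  parts <- lapply(lev, function(l) list(y = y[g == l], d = d[g == l]))
  loglik_group <- function(p, phi) {
    if (sum(p$y) == 0) return(0)  # gamma-hat = 0, degenerate point mass
    gam_ll <- function(gam)
      if (phi == 0) sum(stats::dpois(p$y, p$d * gam, log = TRUE))
      else sum(stats::dnbinom(p$y, mu = p$d * gam, size = 1 / phi, log = TRUE))
    if (max(p$d) - min(p$d) < 1e-12) return(gam_ll(mean(p$y) / p$d[1L]))
    start <- sum(p$y) / sum(p$d)
    stats::optimize(function(g2) -gam_ll(g2),
                    c(start / 50, start * 50))$objective * -1
  }
  prof <- function(lphi) -sum(vapply(parts, loglik_group, numeric(1),
                                     phi = exp(lphi)))
  opt <- stats::optimize(prof, log(interval), tol = 1e-5)
  phi <- exp(opt$minimum)
  if (phi <= interval[1L] * 2 && prof(log(interval[1L])) <= opt$objective + 1e-8)
    phi <- 0
  phi
}

#' Per-gene design parameter estimates
#'
#' For every gene: the normalized control-group mean `mu0`, the fold change
#' `rho` (treatment over control normalized means, with a +0.5 continuity
#' offset to both means when either is zero), the per-gene maximum
#' likelihood dispersion `phi` (floored at 0), and the exact-test p-value of
#' the group sums computed with the pooled common dispersion and the factor
#' ratio `w`.
#'
#' @param counts genes-by-samples count matrix (already filtered).
#' @param group two-level sample labelling, control level first.
#' @param factors per-sample normalization factors; computed by
#'   [norm_factors()] when missing.
#' @param phi_pooled pooled dispersion for the p-values; computed by
#'   [pooled_dispersion()] when missing.
#' @param rule two-sided p-value rule, see [exact_test_pvalue()].
#' @return data frame with columns `gene`, `mu0`, `rho`, `phi`, `pvalue`.
#' @export
estimate_gene_params <- function(counts, group, factors = NULL,
                                 phi_pooled = NULL,
                                 rule = c("smallp", "doubletail")) {
  rule <- match.arg(rule)
  g <- .as_group(group, ncol(counts))
  if (is.null(factors)) factors <- norm_factors(counts)
  if (is.null(phi_pooled)) phi_pooled <- pooled_dispersion(counts, group)
  ctrl <- g == levels(g)[1L]
  n0 <- sum(ctrl); n1 <- sum(!ctrl)
  if (n0 < 2L || n1 < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  norm <- sweep(counts, 2L, factors, "/")
  mu0 <- rowMeans(norm[, ctrl, drop = FALSE])
  mu1 <- rowMeans(norm[, !ctrl, drop = FALSE])
  zero <- mu0 == 0 | mu1 == 0
  rho <- ifelse(zero, (mu1 + 0.5) / (mu0 + 0.5), mu1 / mu0)
  phi <- vapply(seq_len(nrow(counts)), function(i)
    .phi_mle_gene(counts[i, ], factors, g), numeric(1))
  w <- ratio_w(factors, g)
  s1 <- rowSums(counts[, !ctrl, drop = FALSE])
  s0 <- rowSums(counts[, ctrl, drop = FALSE])
  pv <- .pvalues_group_sums(s1, s0, n1, n0, w, phi_pooled, rule = rule)
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("gene%05d", seq_len(nrow(counts)))
  data.frame(gene = ids, mu0 = mu0, rho = rho, phi = phi, pvalue = pv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the prognostic gene set
#'
#' The `ceiling(proportion * m)` genes with the smallest exact-test
#' p-values; ties are broken by larger `|log2(rho)|`, then lexicographic
#' gene identifier.
#'
#' @param params per-gene estimates from [estimate_gene_params()].
#' @param proportion fraction of genes assumed prognostic, in (0, 1).
#' @return character vector of selected gene identifiers.
#' @export
select_prognostic <- function(params, proportion = 0.01) {
  if (!is.numeric(proportion) || proportion <= 0 || proportion >= 1)
    stop("'proportion' must be in (0, 1)", call. = FALSE)
  k <- ceiling(proportion * nrow(params))
  ord <- order(params$pvalue, -abs(log2(params$rho)), params$gene)
  params$gene[ord[seq_len(k)]]
}

#' Fit design parameters to pilot count data
#'
#' Runs the full pilot workflow: low-count filtering, normalization factors,
#' the group factor ratio `w`, pooled and per-gene dispersions, per-gene
#' fold changes and exact-test p-values, prognostic gene selection, and the
#' conservative design triple over the prognostic set.
#'
#' @inheritParams estimate_gene_params
#' @param min_total low-count filter threshold, see
#'   [filter_low_count_genes()].
#' @param norm_method normalization method, see [norm_factors()].
#' @param proportion prognostic fraction, see [select_prognostic()].
#' @return an object of class `"nb_pilot"`: per-gene estimates (`genes`,
#'   with a `prognostic` flag), `factors`, `w`, `phi_pooled`, the
#'   `conservative` triple, and bookkeeping.
#' @examples
#' \donttest{
#' sim <- simulate_counts(simulation_design(m = 200, m1 = 20, n = 4,
#'                                          mu0 = 8, rho = 3, phi = 0.2,
#'                                          f = 0.05, seed = 1))
#' fit <- pilot_fit(sim$counts, sim$group)
#' coef(fit)
#' }
#' @export
pilot_fit <- function(counts, group, min_total = 5,
                      norm_method = c("TMM", "libsize"), proportion = 0.01,
                      rule = c("smallp", "doubletail")) {
  norm_method <- match.arg(norm_method)
  rule <- match.arg(rule)
  g <- .as_group(group, ncol(counts))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers", call. = FALSE)
  kept <- filter_low_count_genes(counts, g, min_total = min_total)
  d <- norm_factors(kept, method = norm_method)
  w <- ratio_w(d, g)
  phi_pooled <- pooled_dispersion(kept, g)
  genes <- estimate_gene_params(kept, g, factors = d,
                                phi_pooled = phi_pooled, rule = rule)
  prog <- select_prognostic(genes, proportion = proportion)
  genes$prognostic <- genes$gene %in% prog
  sel <- genes[genes$prognostic, ]
  triple <- conservative_triple(sel$rho, sel$mu0, sel$phi)
  structure(list(genes = genes, factors = d, w = w, phi_pooled = phi_pooled,
                 conservative = triple, prognostic = prog,
                 m = nrow(genes), m1 = length(prog), group = g,
                 min_total = min_total, norm_method = norm_method,
                 proportion = proportion),
            class = "nb_pilot")
}

#' @export
print.nb_pilot <- function(x, ...) {
  cat("Pilot-data design estimates (NB exact test)\n")
  cat(sprintf("  %d genes after filtering (> %g reads per group), %d samples\n",
              x$m, x$min_total, length(x$factors)))
  cat(sprintf("  normalization: %s; w = %.4g; pooled dispersion = %.4g\n",
              x$norm_method, x$w, x$phi_pooled))
  cat(sprintf("  prognostic set: %d genes (top %.3g%% by p-value)\n",
              x$m1, 100 * x$proportion))
  cat(sprintf("  conservative triple: rho* = %.4g, mu0* = %.4g, phi* = %.4g\n",
              x$conservative["rho"], x$conservative["mu0"],
              x$conservative["phi"]))
  invisible(x)
}

#' @export
summary.nb_pilot <- function(object, ...) {
  print(object)
  cat("\nPer-gene estimate quantiles:\n")
  print(vapply(object$genes[c("mu0", "rho", "phi")],
               stats::quantile, numeric(5), probs = c(0, .25, .5, .75, 1)))
  invisible(object)
}

#' @export
coef.nb_pilot <- function(object, ...) {
  c(object$conservative, w = unname(object$w))
}

#' Write per-gene pilot estimates as TSV
#'
#' @param x an `"nb_pilot"` fit.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gene_estimates <- function(x, file) {
  stopifnot(inherits(x, "nb_pilot"))
  utils::write.table(x$genes, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
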