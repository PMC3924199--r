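.grp <- function(n0, n1) factor(rep(c("control", "treatment"), c(n0, n1)),
                                levels = c("control", "treatment"))

test_that("low-count filter keeps genes exceeding the threshold in both groups", {
  counts <- rbind(
    g1 = c(2, 3, 50, 50),    # control total 5: removed at min_total = 5
    g2 = c(3, 3, 3, 3),      # totals (6, 6): boundary, kept
    g3 = c(50, 50, 2, 3),    # treatment total 5: removed
    g4 = c(10, 10, 10, 10))
  kept <- filter_low_count_genes(counts, .grp(2, 2), min_total = 5)
  expect_identical(rownames(kept), c("g2", "g4"))
  expect_error(filter_low_count_genes(matrix(0, 3, 4), .grp(2, 2)),
               "no genes left")
})

test_that("normalization factors: identity, pure depth, TMM oracle, geometric mean", {
  set.seed(11)
  base <- rnbinom(400, mu = 50, size = 5) + 1
  same <- cbind(base, base, base, base)
  expect_equal(unname(norm_factors(same)), rep(1, 4), tolerance = 1e-10)
  # a pure depth doubling is fully absorbed by the factor
  depth <- cbind(base, 2 * base, base, 2 * base)
  d <- norm_factors(depth)
  expect_equal(unname(d[2] / d[1]), 2, tolerance = 1e-10)
  # randomized matrix against the direct trimmed-mean formula
  y <- matrix(rnbinom(400 * 6, mu = 80, size = 2) + 1, 400, 6)
  f_pkg <- norm_factors(y)
  f_direct <- colSums(y) * oracle_tmm(y)
  f_direct <- f_direct / exp(mean(log(f_direct)))
  expect_equal(unname(f_pkg), unname(f_direct), tolerance = 1e-8)
  expect_equal(exp(mean(log(f_pkg))), 1, tolerance = 1e-10)
  expect_error(norm_factors(cbind(base, 0 * base)), "all-zero")
})

test_that("w is the ratio of group geometric means and hits a constructed target", {
  expect_equal(ratio_w(c(1, 1, 1, 1), .grp(2, 2)), 1)
  expect_equal(ratio_w(c(1, 1, 2, 2), .grp(2, 2)), 2)
  # fixture built with known depths whose geometric-mean ratio is 0.9
  set.seed(21)
  m <- 2000
  mu <- rnbinom(m, mu = 20, size = 3) + 5
  depths <- c(1, 1.05, 0.95, 1, 0.9, 0.945, 0.855, 0.9)  # ratio exactly 0.9
  counts <- vapply(depths, function(dd)
    rnbinom(m, mu = dd * mu, size = 10), numeric(m))
  w <- ratio_w(norm_factors(counts), .grp(4, 4))
  expect_equal(w, 0.9, tolerance = 0.01)
})

test_that("gene estimates are invariant to rescaling one sample's column", {
  set.seed(31)
  counts <- matrix(rnbinom(200 * 6, mu = 30, size = 2) + 1, 200, 6)
  rownames(counts) <- sprintf("g%03d", 1:200)
  g <- .grp(3, 3)
  scaled <- counts; scaled[, 3] <- scaled[, 3] * 3
  # library-size factors absorb a pure depth change exactly
  e1 <- estimate_gene_params(counts, g, factors = norm_factors(counts, "libsize"),
                             phi_pooled = 0.5)
  e2 <- estimate_gene_params(scaled, g, factors = norm_factors(scaled, "libsize"),
                             phi_pooled = 0.5)
  expect_equal(e1$rho, e2$rho, tolerance = 1e-6)
  # with factors constrained to geometric mean 1, the depth change shifts
  # every mu0 by the same known constant (3^(1/6) for one of six columns)
  expect_equal(e2$mu0 / e1$mu0, rep(3^(1 / 6), nrow(counts)), tolerance = 1e-6)
  # TMM absorbs it too, up to its inverse-variance trim weights
  t1 <- estimate_gene_params(counts, g, phi_pooled = 0.5)
  t2 <- estimate_gene_params(scaled, g, phi_pooled = 0.5)
  expect_equal(t1$rho, t2$rho, tolerance = 0.05)
})

test_that("fold change and dispersion estimators recover simulated truth", {
  g <- .grp(50, 50)
  # equal columns in both groups: fold change exactly 1
  set.seed(41)
  half <- matrix(rnbinom(20 * 50, mu = 10, size = 2), 20, 50)
  eq <- estimate_gene_params(cbind(half, half), g, factors = rep(1, 100),
                             phi_pooled = 0.5)
  expect_equal(eq$rho, rep(1, 20))
  # Poisson genes: dispersion estimate collapses toward zero
  pois <- matrix(rpois(10 * 100, 20), 10, 100)
  ep <- estimate_gene_params(pois, g, factors = rep(1, 100), phi_pooled = 0)
  expect_true(all(ep$phi < 0.02))
  # overdispersed gene at phi = 0.5, mu = 10, n = 100/group
  set.seed(43)
  nb <- matrix(rnbinom(5 * 200, mu = 10, size = 2), 5, 200)
  en <- estimate_gene_params(nb, .grp(100, 100), factors = rep(1, 200),
                             phi_pooled = 0.5)
  expect_true(all(en$phi > 0.35 & en$phi < 0.65))
})

test_that("parameter recovery on generator output meets stated tolerances", {
  des <- simulation_design(m = 80, m1 = 40, n = 100, mu0 = 8, rho = 3,
                           phi = 0.4, f = 0.05, seed = 5)
  sim <- simulate_counts(des)
  est <- estimate_gene_params(sim$counts, sim$group,
                              factors = rep(1, 200), phi_pooled = 0.4)
  expect_lt(median(abs(est$phi - 0.4) / 0.4), 0.25)
  rho_err <- abs(est$rho[sim$prognostic] - 3) / 3
  expect_lt(median(rho_err), 0.10)
})

test_that("pooled dispersion is consistent and floors at the Poisson boundary", {
  des <- simulation_design(m = 2000, m1 = 0, n = 10, mu0 = 10, rho = 1,
                           phi = 0.3, f = 0.05, seed = 9)
  sim <- simulate_counts(des)
  expect_equal(pooled_dispersion(sim$counts, sim$group), 0.3, tolerance = 0.05)
  pois <- simulate_counts(simulation_design(m = 2000, m1 = 0, n = 10,
                                            mu0 = 10, rho = 1, phi = 0,
                                            f = 0.05, seed = 9))
  expect_lt(pooled_dispersion(pois$counts, pois$group), 0.005)
})

test_that("prognostic selection counts by ceiling and breaks ties as documented", {
  params <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    mu0 = 1, rho = c(2, 8, 0.5, 1, 4),
    phi = 0.1,
    pvalue = c(0.01, 0.001, 0.001, 0.5, 0.2))
  # ceiling(0.4 * 5) = 2: smallest p first; tie at 0.001 -> larger |log2 rho|
  expect_identical(select_prognostic(params, 0.4), c("b", "c"))
  # tie between b (rho 8) and c (rho 0.5): |log2| 3 vs 1 -> b first
  expect_identical(select_prognostic(params, 0.2), "b")
  expect_error(select_prognostic(params, 0), "proportion")
})

test_that("count matrix IO round-trips and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  counts <- matrix(5:16, 3, 4,
                   dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  write.table(data.frame(gene = rownames(counts), counts),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_count_matrix(f)
  expect_equal(unname(back), unname(counts))
  expect_identical(rownames(back), rownames(counts))
  dup <- f
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), dup)
  expect_error(read_count_matrix(dup), "duplicate")
  writeLines(c("gene\ts1\ts2", "g1\t1\t-2"), dup)
  expect_error(read_count_matrix(dup), "nonnegative")
})

test_that("pilot_fit runs the full workflow end to end", {
  des <- simulation_design(m = 120, m1 = 12, n = 4, mu0 = 10, rho = 4,
                           phi = 0.2, f = 0.05, seed = 3)
  sim <- simulate_counts(des)
  fit <- pilot_fit(sim$counts, sim$group, proportion = 0.05)
  expect_s3_class(fit, "nb_pilot")
  expect_identical(fit$m1, length(fit$prognostic))
  expect_identical(fit$m1, as.integer(ceiling(0.05 * fit$m)))
  expect_true(all(c("rho", "mu0", "phi", "w") %in% names(coef(fit))))
  # strong simulated effects: selection should be enriched in true positives
  truth <- rownames(sim$counts)[sim$prognostic]
  expect_gt(mean(fit$prognostic %in% truth), 0.5)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_gene_estimates(fit, out)
  expect_identical(nrow(read.delim(out)), fit$m)
})
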