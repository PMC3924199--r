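test_that("generator matches NB moments and honours truth labels", {
  # Poisson limit: variance equals mean
  pois <- simulate_counts(simulation_design(m = 2, m1 = 0, n = 5000,
                                            mu0 = 5, rho = 1, phi = 0,
                                            f = 0.05, seed = 13))
  expect_equal(var(c(pois$counts)) / mean(c(pois$counts)), 1, tolerance = 0.05)
  expect_false(any(pois$prognostic))
  # overdispersed: variance within 5% of mu (1 + mu phi) at 1e5 draws
  nb <- simulate_counts(simulation_design(m = 10, m1 = 0, n = 5000,
                                          mu0 = 5, rho = 1, phi = 0.5,
                                          f = 0.05, seed = 13))
  expect_equal(var(c(nb$counts)), 5 * (1 + 5 * 0.5), tolerance = 0.05)
  # prognostic genes carry the fold change; null genes do not
  des <- simulation_design(m = 400, m1 = 100, n = 50, mu0 = 10, rho = 3,
                           phi = 0.1, f = 0.05, seed = 17)
  sim <- simulate_counts(des)
  trt <- sim$group == "treatment"
  expect_equal(mean(sim$counts[sim$prognostic, trt]), 30, tolerance = 0.05)
  expect_equal(mean(sim$counts[!sim$prognostic, trt]), 10, tolerance = 0.05)
  # w scales every treatment mean (depth imbalance)
  dw <- simulate_counts(simulation_design(m = 400, m1 = 0, n = 50, mu0 = 10,
                                          rho = 1, phi = 0.1, w = 0.8,
                                          f = 0.05, seed = 17))
  expect_equal(mean(dw$counts[, dw$group == "treatment"]), 8, tolerance = 0.05)
})

test_that("generator is bitwise deterministic in (seed, replicate)", {
  des <- simulation_design(m = 50, m1 = 5, n = 4, mu0 = 5, rho = 2,
                           phi = 0.2, f = 0.05, reps = 3, seed = 101)
  expect_identical(simulate_counts(des, 2), simulate_counts(des, 2))
  expect_false(identical(simulate_counts(des, 1)$counts,
                         simulate_counts(des, 2)$counts))
  # distinct base seeds give distinct streams
  des2 <- simulation_design(m = 50, m1 = 5, n = 4, mu0 = 5, rho = 2,
                            phi = 0.2, f = 0.05, reps = 3, seed = 102)
  expect_false(identical(simulate_counts(des, 1)$counts,
                         simulate_counts(des2, 1)$counts))
})

test_that("q-values follow the Storey formula with cap, floor and monotonicity", {
  expect_identical(qvalues(rep(1, 8)), rep(1, 8))
  # degenerate pi0 estimate: floored at 1/m, not zero
  p3 <- c(0.01, 0.02, 0.03)
  expect_equal(qvalues(p3), rep(0.01, 3))
  set.seed(7)
  p <- runif(1000)
  q <- qvalues(p)
  expect_equal(q, oracle_qvalue(p), tolerance = 1e-10)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))  # p_i <= p_j  =>  q_i <= q_j
  expect_true(all(q >= 0 & q <= 1))
  expect_error(qvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(qvalues(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(qvalues(numeric(0)), "empty")
})

test_that("validation harness is deterministic and controls false rejections", {
  des <- simulation_design(m = 300, m1 = 10, n = 4, mu0 = 5, rho = 4,
                           phi = 0.2, f = 0.05, reps = 2, seed = 23)
  r1 <- run_validation(des)
  r2 <- run_validation(des)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(nrow(r1$replicates), 2L)
  expect_true(all(r1$replicates$R1 <= 10), all(r1$replicates$R0 <= 290))
  # global null: rejections should be rare under q-value control
  null_des <- simulation_design(m = 1000, m1 = 0, n = 4, mu0 = 5, rho = 1,
                                phi = 0.2, f = 0.05, reps = 30, seed = 29)
  nres <- run_validation(null_des, norm_method = "libsize")
  expect_identical(nres$r1_hat, 0)
  frac_any <- mean(nres$replicates$R > 0)
  expect_lte(frac_any, 0.05 + 3 * sqrt(0.05 * 0.95 / 30))
})

test_that("harness detects strong effects and keeps empirical FDR near nominal", {
  des <- simulation_design(m = 800, m1 = 40, n = 6, mu0 = 5, rho = 4,
                           phi = 0.1, f = 0.05, reps = 5, seed = 37)
  res <- run_validation(des)
  expect_gt(res$r1_hat, 20)        # high power regime by design
  with_rej <- res$replicates$R > 0
  fdp <- res$replicates$R0[with_rej] / res$replicates$R[with_rej]
  se <- sd(fdp) / sqrt(sum(with_rej))
  expect_lte(res$empirical_fdr, 0.05 + 3 * max(se, 0.02))
  # dispersion and w estimated inside the loop land near truth
  expect_equal(res$phi_hat, 0.1, tolerance = 0.5)
  expect_equal(res$w_hat, 1, tolerance = 0.05)
})

test_that("simulate() on a solved FDR design yields matrices at the solved n", {
  fit <- nb_sample_size_fdr(m = 500, m1 = 5, r1 = 4, f = 0.05,
                            rho = 4, mu0 = 5, phi = 0.1)
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_identical(dim(sims[[1]]$counts), c(500L, 2L * fit$n))
})
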