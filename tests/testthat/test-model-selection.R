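test_that("the printed w bound evaluates exactly", {
  expect_equal(w_upper_bound_printed(k = 2, D = 2, alpha = 0, c_min = 1), 1)
  expect_equal(w_upper_bound_printed(k = 3, D = 3, alpha = 0.5, c_min = 1),
               1.875)
  # alpha = 0: independent of D
  expect_equal(w_upper_bound_printed(4, 1, 0, 2),
               w_upper_bound_printed(4, 6, 0, 2))
  expect_error(w_upper_bound_printed(1, 2), "at least 2")
})

test_that("the implemented bound certifies a PSD Hessian", {
  set.seed(51)
  for (trial in 1:60) {
    k <- sample(2:6, 1); D <- sample(1:4, 1)
    a <- runif(1, 0, 5); c_min <- sample(1:10, 1)
    w <- w_upper_bound_implemented(k, D, a, c_min)
    counts <- c_min + sample(0:10, k, replace = TRUE)
    counts[sample(k, 1)] <- c_min
    H <- scVDMC:::center_hessian(counts, D, w, a)
    expect_gte(min(eigen(H, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
    # monotone in c_min
    expect_gte(w_upper_bound_implemented(k, D, a, c_min + 1), w)
  }
  # w = 0: H is a non-negative diagonal plus a non-negative multiple of I
  H0 <- scVDMC:::center_hessian(c(3, 1, 2), 3, 0, 2)
  expect_gte(min(eigen(H0, only.values = TRUE)$values), 0)
})

test_that("elbow statistic is the selected-gene within-cluster SS", {
  # two cells at 0 and 2 in one cluster with center 1 on the selected gene
  X <- rbind(c(0, 2), c(5, 7))
  ds <- toy_dataset(list(X))
  res <- list(U = list(cbind(c(1, 6))), V = list(rbind(1, 1)),
              B = c(1, 0))
  expect_equal(elbow_statistic(ds, res), 2)
  # identity with the objective's reconstruction term
  inst <- rand_instance(m = 6, k = 2, D = 2, n = 7, seed = 52)
  B <- c(1, 0, 1, 1, 0, 1)
  res2 <- list(U = inst$U, V = inst$V, B = B)
  obj <- scvdmc_objective(inst$dataset, inst$U, inst$V, B)
  expect_equal(elbow_statistic(inst$dataset, res2),
               2 * obj$reconstruction)
  # cells exactly at their centers
  U <- cbind(c(1, 2), c(3, 4))
  V <- rbind(c(1, 0), c(0, 1))
  ds3 <- toy_dataset(list(tcrossprod(U, V)))
  expect_equal(elbow_statistic(ds3, list(U = list(U), V = list(V),
                                         B = c(1, 1))), 0)
})

test_that("elbow scan decreases with k and returns one row per k", {
  sim <- simulate_multidomain(simulation_config(
    D = 2, cells_per_domain = c(25, 25), k_true = 3, m_total = 80,
    seed = 4))
  sc <- elbow_scan(sim$dataset, k_values = c(2, 3, 4, 5), lambda = 2,
                   w = 1, alpha = 1, repeats = 3, seed = 1)
  expect_equal(sc$k, c(2, 3, 4, 5))
  expect_lte(cor(sc$k, sc$mean_ts, method = "spearman"), 0)
  # single k: the scan equals the statistic of one fit
  sc1 <- elbow_scan(sim$dataset, k_values = 3, lambda = 2, w = 1,
                    alpha = 1, repeats = 1, seed = 7)
  fit <- scvdmc(sim$dataset, k = 3, lambda = 2, w = 1, alpha = 1, seed = 7)
  expect_equal(sc1$mean_ts, elbow_statistic(sim$dataset, fit))
})

test_that("the agreement diagnostic measures matched-center distance", {
  U1 <- cbind(c(1, 2, 9)); U2 <- cbind(c(4, 6, 9))
  res <- list(U = list(U1, U2), B = c(1, 1, 0))
  expect_equal(alpha_diagnostic(res), 5)       # sqrt(3^2 + 4^2)
  # identical centers -> 0
  expect_equal(alpha_diagnostic(list(U = list(U1, U1), B = c(1, 1, 0))), 0)
  # invariant to a common rigid shift of all centers
  res_shift <- list(U = lapply(res$U, function(u) u + 13), B = res$B)
  expect_equal(alpha_diagnostic(res_shift), alpha_diagnostic(res))
  expect_error(alpha_diagnostic(list(U = list(U1), B = c(1, 1, 0))),
               "two domains")
})

test_that("suggest_w sits below the balanced-cluster bound", {
  sim <- simulate_multidomain(simulation_config(
    D = 2, cells_per_domain = c(20, 24), k_true = 2, m_total = 40,
    seed = 2))
  w <- suggest_w(sim$dataset, k = 2, alpha = 1)
  expect_lt(w, w_upper_bound_implemented(2, 2, 1, c_min = 10))
  expect_gt(w, 0)
})
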