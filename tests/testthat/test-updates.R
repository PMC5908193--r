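test_that("cells go to the nearest center on the selected genes only", {
  # distances measured only where B = 1
  U <- cbind(c(0, 0), c(10, 0))
  dom <- expression_domain(cbind(c(4, 0), c(6, 0)), "d1")
  V <- update_assignments(dom, U, c(1, 1))
  expect_equal(max.col(V), c(1, 2))
  # exact match with a center -> that cluster
  dom2 <- expression_domain(cbind(c(10, 0)), "d1")
  expect_equal(max.col(update_assignments(dom2, U, c(1, 1))), 2)
  # centers differing only in a non-selected gene -> tie -> cluster 1
  U3 <- cbind(c(0, 0), c(0, 5))
  dom3 <- expression_domain(matrix(rnorm(8), 2, 4), "d1")
  V3 <- update_assignments(dom3, U3, c(1, 0))
  expect_true(all(max.col(V3) == 1))
  expect_error(update_assignments(dom3, U3, c(0, 0)), "at least one")
})

test_that("assignments match the brute-force oracle on random instances", {
  set.seed(11)
  for (trial in 1:40) {
    m <- sample(2:20, 1); k <- sample(2:5, 1); n <- sample(1:12, 1)
    X <- matrix(rnorm(m * n), m, n)
    U <- matrix(rnorm(m * k), m, k)
    B <- numeric(m); B[sample(m, sample(m, 1))] <- 1
    dom <- expression_domain(X, "d")
    expect_identical(update_assignments(dom, U, B), oracle_assign(X, U, B))
  }
})

test_that("empty clusters are refilled by splitting the largest cluster", {
  V <- diag(2)[c(1, 2, 1, 2), ]
  set.seed(1)
  expect_identical(repair_empty_clusters(V), V)   # no-op when none empty
  V1 <- matrix(0, 4, 2); V1[, 1] <- 1
  set.seed(1)
  R1 <- repair_empty_clusters(V1)
  expect_equal(sort(colSums(R1)), c(2, 2))        # equal halves
  expect_true(all(rowSums(R1) == 1))
  V2 <- matrix(0, 3, 3); V2[, 1] <- 1
  set.seed(2)
  R2 <- repair_empty_clusters(V2)
  expect_equal(sort(colSums(R2)), c(1, 1, 1))     # two successive splits
  expect_error(repair_empty_clusters(matrix(c(1, 0), 1, 2)), "populate")
})

test_that("center update reduces to per-cluster means without penalties", {
  inst <- rand_instance(m = 5, k = 3, D = 1, n = 9, seed = 5)
  U1 <- update_centers(1, inst$dataset, inst$V, inst$U, rep(1, 5),
                       w = 0, alpha = 0)
  X <- inst$dataset$domains[[1]]$values
  means <- sapply(1:3, function(j)
    rowMeans(X[, inst$V[[1]][, j] == 1, drop = FALSE]))
  expect_equal(unname(U1), unname(means), tolerance = 1e-12)
  # single domain: alpha cannot matter
  U2 <- update_centers(1, inst$dataset, inst$V, inst$U, rep(1, 5),
                       w = 0.2, alpha = 57)
  U3 <- update_centers(1, inst$dataset, inst$V, inst$U, rep(1, 5),
                       w = 0.2, alpha = 0)
  expect_equal(U2, U3)
})

test_that("center update is the numerical minimizer of the row objective", {
  skip_if_not_installed("pracma")
  set.seed(21)
  for (trial in 1:15) {
    inst <- rand_instance(m = 3, k = 2, D = 2, n = 4,
                          seed = 300 + trial)
    w <- 0.1; a <- 0.5
    Unew <- update_centers(1, inst$dataset, inst$V, inst$U, rep(1, 3),
                           w = w, alpha = a)
    for (i in 1:3) {
      f <- function(u) row_objective(u, inst$dataset, 1, i, inst$V,
                                     inst$U, w, a)
      g <- pracma::grad(f, Unew[i, ])
      expect_lt(max(abs(g)), 1e-6)
      opt <- optim(rep(mean(inst$dataset$domains[[1]]$values[i, ]), 2), f,
                   method = "BFGS",
                   control = list(reltol = 1e-15, maxit = 2000))
      expect_equal(unname(Unew[i, ]), unname(opt$par), tolerance = 1e-6)
    }
  }
})

test_that("center update refuses empty clusters and singular systems", {
  inst <- rand_instance(m = 4, k = 2, D = 2, n = 6, seed = 9)
  Vbad <- inst$V; Vbad[[1]][, 2] <- 0; Vbad[[1]][, 1] <- 1
  expect_error(update_centers(1, inst$dataset, Vbad, inst$U, rep(1, 4)),
               "empty cluster")
  # with equal cluster sizes c and alpha = 0, H = diag(c) - (2w/k) Psi is
  # exactly singular at w = c k / 2
  Veq <- inst$V
  Veq[[1]] <- diag(2)[rep(1:2, each = 3), ]
  c_eq <- 3
  expect_error(
    update_centers(1, inst$dataset, Veq, inst$U, rep(1, 4),
                   w = c_eq * 2 / 2, alpha = 0),
    "lower w")
})

test_that("feature selection solves the cardinality-constrained program", {
  # lam = m selects everything
  inst <- rand_instance(m = 4, k = 2, D = 2, n = 5, seed = 13)
  expect_equal(as.numeric(select_features(inst$dataset, inst$U, inst$V,
                                          lambda = 4)), rep(1, 4))
  expect_error(select_features(inst$dataset, inst$U, inst$V, lambda = 5),
               "lambda")
  # matches exhaustive subset search on random instances, all lambda
  for (trial in 1:15) {
    inst <- rand_instance(m = sample(3:7, 1), k = 2, D = 2, n = 5,
                          seed = 400 + trial)
    w <- runif(1); a <- runif(1)
    for (lam in seq_len(inst$m)) {
      B <- select_features(inst$dataset, inst$U, inst$V, w, a, lam)
      expect_equal(as.numeric(B),
                   oracle_select(inst$dataset, inst$U, inst$V, w, a, lam))
    }
  }
})

test_that("coefficient ties break to the lowest gene index", {
  # two identical genes: the first must win
  X <- rbind(c(1, 2, 3), c(1, 2, 3), c(9, 1, 4))
  ds <- toy_dataset(list(X))
  U <- list(matrix(c(1, 1, 5, 3, 3, 2), 3, 2))
  V <- list(rbind(c(1, 0), c(0, 1), c(0, 1)))
  B <- select_features(ds, U, V, lambda = 1)
  expect_equal(which(B == 1), 1L)
})

test_that("each block update never increases the objective", {
  set.seed(77)
  for (trial in 1:100) {
    inst <- rand_instance(m = sample(3:8, 1), k = sample(2:3, 1),
                          D = sample(1:3, 1), n = sample(4:9, 1))
    k <- inst$k; D <- inst$D
    a <- runif(1, 0, 2)
    w <- 0.9 * w_upper_bound_implemented(k, D, a, c_min = 1)
    lam <- sample(inst$m, 1)
    B <- as.numeric(select_features(inst$dataset, inst$U, inst$V, w, a, lam))
    base <- scvdmc_objective(inst$dataset, inst$U, inst$V, B, w, a)$value
    # feature-selection update from a random B of the same cardinality
    Brand <- numeric(inst$m); Brand[sample(inst$m, lam)] <- 1
    vrand <- scvdmc_objective(inst$dataset, inst$U, inst$V, Brand, w, a)$value
    expect_lte(base, vrand + 1e-9)
    # assignment update
    V2 <- inst$V
    V2[[1]] <- update_assignments(inst$dataset$domains[[1]], inst$U[[1]], B)
    v2 <- scvdmc_objective(inst$dataset, inst$U, V2, B, w, a)$value
    expect_lte(v2, base + 1e-9)
    # center update (requires no empty cluster in the updated domain)
    if (all(colSums(V2[[1]]) > 0)) {
      U2 <- inst$U
      U2[[1]] <- update_centers(1, inst$dataset, V2, inst$U, B, w, a)
      v3 <- scvdmc_objective(inst$dataset, U2, V2, B, w, a)$value
      expect_lte(v3, v2 + 1e-9)
    }
  }
})
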