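test_that("the default scenario matches the intended geometry", {
  sim <- simulate_multidomain(simulation_config(seed = 1))
  expect_equal(n_domains(sim$dataset), 3)
  expect_equal(unname(n_cells(sim$dataset)), c(33, 33, 34))
  expect_equal(n_genes(sim$dataset), 1000)
  expect_equal(sim$truth$marker_indices, 1:2)
  expect_true(all(vapply(sim$truth$labels, function(l)
    all(l %in% 1:4), logical(1))))
  # values are shifted non-negative
  expect_true(all(vapply(sim$dataset$domains, function(d)
    min(d$values) >= 0, logical(1))))
})

test_that("simulation is bitwise deterministic given the seed", {
  cfg <- simulation_config(D = 2, cells_per_domain = c(10, 12),
                           m_total = 50, k_true = 3, seed = 77)
  s1 <- simulate_multidomain(cfg)
  s2 <- simulate_multidomain(cfg)
  expect_identical(s1$dataset$domains[[1]]$values,
                   s2$dataset$domains[[1]]$values)
  expect_identical(s1$truth$labels, s2$truth$labels)
  s3 <- simulate_multidomain(simulation_config(
    D = 2, cells_per_domain = c(10, 12), m_total = 50, k_true = 3,
    seed = 78))
  expect_false(identical(s1$dataset$domains[[1]]$values,
                         s3$dataset$domains[[1]]$values))
})

test_that("domain rotations are orthogonal under both samplers", {
  for (rot in c("bounded", "haar")) {
    sim <- simulate_multidomain(simulation_config(
      D = 2, cells_per_domain = c(8, 8), m_total = 30, k_true = 2,
      mixing_dims = 4, rotation = rot, seed = 5))
    for (tr in sim$truth$transforms) {
      R <- tr$rotation
      expect_lt(max(abs(crossprod(R) - diag(nrow(R)))), 1e-10)
    }
  }
})

test_that("marker spread matches the configured within-cluster sd", {
  cfg <- simulation_config(D = 1, cells_per_domain = 200L, k_true = 2,
                           m_total = 20, cluster_spread = 0.5,
                           noise_sd = 0, rotate = FALSE,
                           rescale_range = c(1, 1), seed = 9)
  sim <- simulate_multidomain(cfg)
  X <- sim$dataset$domains[[1]]$values
  lab <- sim$truth$labels[[1]]
  v <- sapply(1:2, function(g)
    mean(sapply(1:2, function(cl) var(X[g, lab == cl]))))
  expect_equal(mean(v), 0.25, tolerance = 0.2 * 0.25)
})

test_that("unmixed non-marker genes carry no label information", {
  cfg <- simulation_config(D = 1, cells_per_domain = 400L, k_true = 2,
                           m_total = 60, seed = 10)
  sim <- simulate_multidomain(cfg)
  X <- sim$dataset$domains[[1]]$values
  lab <- sim$truth$labels[[1]]
  # AUC of each gene as a 1-vs-rest classifier, via the rank statistic
  auc <- function(x, y) {
    r <- rank(x)
    n1 <- sum(y); n0 <- sum(!y)
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  outside <- (cfg$mixing_dims + 1):cfg$m_total
  aucs <- vapply(outside, function(g) auc(X[g, ], lab == 1), numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("pooled k-means on marker genes trails the multitask fit", {
  aris <- sapply(1:10, function(s) {
    sim <- simulate_multidomain(simulation_config(seed = 500 + s))
    ds <- sim$dataset
    pk <- pooled_kmeans(ds, 4, gene_subset = sim$truth$marker_indices,
                        seed = s)
    w <- suggest_w(ds, k = 4, alpha = 1)
    fit <- suppressWarnings(
      scvdmc(ds, k = 4, lambda = 2, w = w, alpha = 1, seed = s,
             nstart = 5))
    c(pooled = mean(mapply(adjusted_rand_index, pk, sim$truth$labels)),
      scvdmc = mean(mapply(adjusted_rand_index, fit$labels,
                           sim$truth$labels)))
  })
  expect_gt(mean(aris["scvdmc", ]), mean(aris["pooled", ]))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(D = 2, cells_per_domain = c(5, 5, 5)),
               "length D")
  expect_error(simulation_config(n_markers = 10, m_total = 10),
               "smaller")
  expect_error(simulation_config(mixing_dims = 1), "mixing_dims")
  expect_error(simulation_config(rescale_range = c(2, 1)), "increasing")
})

test_that("simulations round-trip through the plain-text writer", {
  sim <- simulate_multidomain(simulation_config(
    D = 2, cells_per_domain = c(6, 7), m_total = 12, k_true = 2, seed = 3))
  out <- file.path(tempdir(), "simwrite")
  files <- write_simulation(sim, out)
  expect_true(all(file.exists(files)))
  dom <- read_domain(file.path(out, "domain_1.tsv"))
  expect_equal(dom$values, sim$dataset$domains[[1]]$values,
               tolerance = 1e-15)
  truth <- read.delim(file.path(out, "truth.tsv"))
  expect_equal(nrow(truth), 13)
  expect_equal(readLines(file.path(out, "markers.txt")),
               sim$truth$marker_ids)
})
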