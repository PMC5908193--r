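# Independent oracles used across the suite: naive loop-based
# implementations kept deliberately separate from the package's vectorized
# code paths.

# population variance, naive
naive_popvar <- function(x) sum((x - mean(x))^2) / length(x)

# per-gene selection coefficient by explicit loops
naive_gene_coefficient <- function(dataset, U, V, w, alpha, i) {
  D <- length(dataset$domains)
  recon <- sep <- 0
  for (d in seq_len(D)) {
    X <- dataset$domains[[d]]$values
    pred <- as.numeric(U[[d]][i, ] %*% t(V[[d]]))
    recon <- recon + 0.5 * sum((X[i, ] - pred)^2)
    sep <- sep + naive_popvar(U[[d]][i, ])
  }
  agree <- 0
  for (j in seq_len(ncol(U[[1]]))) {
    y <- vapply(seq_len(D), function(d) U[[d]][i, j], numeric(1))
    agree <- agree + naive_popvar(y)
  }
  recon - w * sep + alpha * agree
}

# full objective by summing naive per-gene coefficients over selected genes
naive_objective <- function(dataset, U, V, B, w, alpha) {
  sum(vapply(which(B == 1), function(i)
    naive_gene_coefficient(dataset, U, V, w, alpha, i), numeric(1)))
}

# brute-force nearest-center assignment, ties to lowest cluster index
oracle_assign <- function(X, U, B) {
  sel <- which(B == 1)
  n <- ncol(X); k <- ncol(U)
  V <- matrix(0, n, k)
  for (c in seq_len(n)) {
    d2 <- vapply(seq_len(k), function(j)
      sum((X[sel, c] - U[sel, j])^2), numeric(1))
    V[c, which.min(d2)] <- 1
  }
  V
}

# exhaustive subset search for the feature-selection subproblem
oracle_select <- function(dataset, U, V, w, alpha, lam) {
  m <- length(dataset$gene_ids)
  co <- vapply(seq_len(m), function(i)
    naive_gene_coefficient(dataset, U, V, w, alpha, i), numeric(1))
  subsets <- utils::combn(m, lam)
  vals <- apply(subsets, 2L, function(s) sum(co[s]))
  best <- subsets[, which.min(vals)]
  B <- numeric(m); B[best] <- 1
  B
}

# all permutations of 1..n (n <= 6 in tests)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# brute-force best one-to-one matching error over all permutations
oracle_error <- function(pred, truth) {
  pred <- as.integer(as.factor(pred)); truth <- as.integer(as.factor(truth))
  tab <- table(factor(pred, levels = seq_len(max(pred))),
               factor(truth, levels = seq_len(max(truth))))
  r <- nrow(tab); s <- ncol(tab)
  big <- max(r, s)
  padded <- matrix(0, big, big)
  padded[seq_len(r), seq_len(s)] <- tab
  best <- 0
  for (p in all_perms(big))
    best <- max(best, sum(padded[cbind(seq_len(big), p)]))
  1 - best / length(pred)
}

# Hubert-Arabie ARI straight from the contingency table
oracle_ari <- function(pred, truth) {
  tab <- table(pred, truth)
  n <- length(pred)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expd <- sa * sb / choose(n, 2)
  (sij - expd) / ((sa + sb) / 2 - expd)
}

# Lloyd's k-means with lowest-index tie-break, recording the label
# sequence; independent of the package solver
oracle_lloyd <- function(X, U0, max_iter = 50L) {
  U <- U0
  labels_seq <- list()
  prev <- NULL
  for (it in seq_len(max_iter)) {
    V <- oracle_assign(X, U, rep(1, nrow(X)))
    lab <- max.col(V, ties.method = "first")
    labels_seq[[it]] <- lab
    for (j in seq_len(ncol(U))) {
      if (sum(V[, j]) > 0)
        U[, j] <- rowMeans(X[, V[, j] == 1, drop = FALSE])
    }
    if (!is.null(prev) && identical(lab, prev)) break
    prev <- lab
  }
  labels_seq
}

# the center-subproblem row objective for domain d, gene i, as a function
# of that row alone (other domains' centers fixed)
row_objective <- function(u, dataset, d, i, V, U, w, alpha) {
  X <- dataset$domains[[d]]$values
  D <- length(dataset$domains)
  val <- 0.5 * sum((X[i, ] - as.numeric(u %*% t(V[[d]])))^2) -
    w * naive_popvar(u)
  for (j in seq_along(u)) {
    y <- vapply(seq_len(D), function(l)
      if (l == d) u[j] else U[[l]][i, j], numeric(1))
    val <- val + alpha * naive_popvar(y)
  }
  val
}

# random multi-domain instance with no empty cluster in any domain
rand_instance <- function(m = 5, k = 2, D = 2, n = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  doms <- lapply(seq_len(D), function(d)
    expression_domain(matrix(abs(rnorm(m * n)), m, n),
                      domain_id = paste0("dom", d)))
  ds <- multidomain_dataset(doms)
  U <- lapply(seq_len(D), function(d) matrix(rnorm(m * k), m, k))
  V <- lapply(seq_len(D), function(d) {
    repeat {
      lab <- sample(seq_len(k), n, replace = TRUE)
      if (length(unique(lab)) == k) break
    }
    V <- matrix(0, n, k); V[cbind(seq_len(n), lab)] <- 1; V
  })
  list(dataset = ds, U = U, V = V, m = m, k = k, D = D, n = n)
}

# small deterministic dataset builders for filter tests
toy_dataset <- function(mats, ids = NULL) {
  doms <- lapply(seq_along(mats), function(d)
    expression_domain(mats[[d]], domain_id = paste0("dom", d)))
  multidomain_dataset(doms, gene_ids = ids)
}
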