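#' Assign cells to their nearest centers on the selected genes
#'
#' The assignment subproblem of the alternating solver: with centers and the
#' marker selection fixed, each cell is assigned (one-hot) to the cluster
#' whose center is nearest in squared Euclidean distance computed only over
#' genes with `B == 1`. Ties go to the lowest cluster index.
#'
#' @param domain An [expression_domain()].
#' @param U Genes x k center matrix for this domain.
#' @param B Binary selection vector (at least one gene selected).
#' @return Binary cells x k one-hot assignment matrix.
#' @export
update_assignments <- function(domain, U, B) {
  X <- domain$values
  B <- check_selection(B, nrow(X))
  if (sum(B) < 1) stop("B selects no genes; at least one is required")
  sel <- B == 1
  Xs <- X[sel, , drop = FALSE]
  Us <- U[sel, , drop = FALSE]
  # d^2(c, j) = ||x_c||^2 - 2 x_c.u_j + ||u_j||^2; the ||x_c||^2 term is
  # constant per cell and dropped before the argmin
  score <- -2 * crossprod(Xs, Us)                       # n x k
  score <- sweep(score, 2L, colSums(Us * Us), `+`)
  assign <- max.col(-score, ties.method = "first")
  onehot(assign, ncol(U))
}

# internal: labels -> one-hot matrix
onehot <- function(labels, k) {
  V <- matrix(0, nrow = length(labels), ncol = k)
  V[cbind(seq_along(labels), labels)] <- 1
  V
}

# internal: one-hot matrix -> labels
hard_labels <- function(V) max.col(V, ties.method = "first")

#' Re-populate empty clusters by splitting the largest cluster
#'
#' If a cluster loses all members during an assignment update, the members
#' of the largest cluster are randomly bipartitioned into equal halves (odd
#' remainder stays) and one half is moved to the empty cluster; this repeats
#' until all k clusters are non-empty. Uses the current RNG stream, so the
#' split is deterministic under a fixed seed.
#'
#' @param V Binary cells x k one-hot assignment matrix.
#' @return One-hot matrix of the same shape with no empty column.
#' @export
repair_empty_clusters <- function(V) {
  n <- nrow(V); k <- ncol(V)
  if (n < k) stop("cannot populate ", k, " clusters with only ", n, " cells")
  sizes <- colSums(V)
  while (any(sizes == 0)) {
    empty <- which(sizes == 0)[1L]
    largest <- which.max(sizes)             # ties -> lowest index
    members <- which(V[, largest] == 1)
    move <- sample(members, size = length(members) %/% 2L)
    V[move, largest] <- 0
    V[move, empty] <- 1
    sizes <- colSums(V)
  }
  V
}

#' Solve the center subproblem for one domain
#'
#' With assignments and the marker selection fixed, each selected gene's
#' center row is the unique stationary point of the row objective
#' \deqn{\frac12\|X_{i,:} - u V^\top\|^2 - w\,\mathrm{Var}(u)
#'       + \alpha \sum_j \mathrm{Var}(Y^{(i,j)}),}
#' obtained by solving the k x k linear system `H u' = rhs` with
#' \deqn{H = V^\top V - \frac{2w}{k}\Psi + \frac{2\alpha}{D}\Phi_{dd} I_k,}
#' where `Psi` and `Phi` are the k- and D-dimensional centering matrices.
#' `H` is shared across genes, so it is factorized once per call.
#' Non-selected genes do not enter the objective; their rows are kept
#' well-defined as ordinary per-cluster means so that they re-enter feature
#' selection with up-to-date coefficients.
#'
#' With `alpha_scaling = "printed"` the agreement terms in `H` and the
#' right-hand side are multiplied by an extra factor k, matching the closed
#' form printed in the original description of the method (see the methods
#' vignette for why the default derives the system from the objective
#' instead).
#'
#' @param d Domain index (1-based).
#' @param dataset A [multidomain_dataset()].
#' @param V List of D one-hot assignment matrices; `V[[d]]` must have no
#'   empty cluster.
#' @param U List of D current center matrices (the other domains' centers
#'   enter through the agreement coupling).
#' @param B Binary selection vector.
#' @param w,alpha Non-negative weights.
#' @param alpha_scaling `"derived"` (default) or `"printed"`.
#' @return Updated genes x k center matrix for domain `d`.
#' @export
update_centers <- function(d, dataset, V, U, B, w = 0, alpha = 0,
                           alpha_scaling = c("derived", "printed")) {
  alpha_scaling <- match.arg(alpha_scaling)
  k <- check_fit_shapes(dataset, U, V)
  m <- n_genes(dataset)
  B <- check_selection(B, m)
  X <- dataset$domains[[d]]$values
  Vd <- V[[d]]
  D <- n_domains(dataset)
  counts <- colSums(Vd)
  if (any(counts == 0))
    stop("domain '", names(dataset$domains)[d],
         "': empty cluster in V; repair before updating centers")
  a <- if (alpha_scaling == "printed") alpha * k else alpha
  XV <- X %*% Vd                                         # m x k
  # per-cluster means, used for non-selected rows (and as the w=alpha=0 case)
  means <- sweep(XV, 2L, counts, `/`)
  Unew <- means
  sel <- B == 1
  if (any(sel)) {
    Psi <- diag(k) - matrix(1 / k, k, k)
    phi_dd <- if (D > 1) (1 - 1 / D) else 0
    H <- diag(counts, k) - (2 * w / k) * Psi + (2 * a / D) * phi_dd * diag(k)
    RHS <- t(XV[sel, , drop = FALSE])                    # k x m_sel
    if (D > 1) {
      # sum_{l != d} Phi[d, l] U^(l)[i,]' = -(1/D) sum_{l != d} U^(l)[i,]'
      S <- Reduce(`+`, U[-d])[sel, , drop = FALSE]
      RHS <- RHS + (2 * a / D^2) * t(S)
    }
    sol <- tryCatch(solve(H, RHS), error = function(e)
      stop("center subproblem is singular (H not invertible); ",
           "lower w below the PSD bound (see w_upper_bound_implemented)",
           call. = FALSE))
    Unew[sel, ] <- t(sol)
  }
  dimnames(Unew) <- list(dataset$gene_ids, NULL)
  Unew
}

#' Select the marker genes minimizing the objective at fixed U, V
#'
#' The feature-selection subproblem is a cardinality-constrained binary
#' linear program: each gene i receives the coefficient
#' \deqn{c_i = \frac12\sum_d \|X^{(d)}_{i,:} - U^{(d)}_{i,:}V^{(d)\top}\|^2
#'       - w\sum_d \mathrm{Var}(U^{(d)}_{i,:})
#'       + \alpha\sum_j \mathrm{Var}(Y^{(i,j)}),}
#' and the lambda genes with the smallest coefficients are selected (a sort
#' solves the program exactly). Ties go to the lowest gene index.
#'
#' @inheritParams scvdmc_objective
#' @param lambda Number of genes to select, in `[1, n_genes]`.
#' @return Binary vector of length `n_genes(dataset)` with exactly `lambda`
#'   ones, carrying the per-gene coefficients as attribute `"coefficients"`.
#' @export
select_features <- function(dataset, U, V, w = 0, alpha = 0, lambda) {
  m <- n_genes(dataset)
  lambda <- as.integer(lambda)
  if (lambda < 1L || lambda > m)
    stop("'lambda' must be in [1, ", m, "]; got ", lambda)
  co <- gene_coefficients(dataset, U, V, w, alpha)$coefficient
  B <- numeric(m)
  B[order(co)[seq_len(lambda)]] <- 1      # radix order: stable, ties -> low i
  attr(B, "coefficients") <- co
  B
}
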