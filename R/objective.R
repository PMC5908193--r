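#' Population variance of a center row
#'
#' The within-domain separation term scores each gene by the population
#' variance of its k cluster-center values, written as the centering
#' quadratic form (1/k) u (I_k - (1/k) 1 1') u'.
#'
#' @param u Numeric vector of length k (one gene's centers across clusters).
#' @return Non-negative scalar population variance.
#' @export
row_variance <- function(u) {
  if (length(u) == 0L) stop("'u' must be a non-empty numeric vector")
  u <- as.numeric(u)
  mean((u - mean(u))^2)
}

#' Population variance of a center entry across domains
#'
#' The cross-domain agreement term penalizes, for each selected gene i and
#' cluster j, the population variance of the stacked center entries
#' (U^(1)[i,j], ..., U^(D)[i,j]) over the D domains. It is zero for a single
#' domain.
#'
#' @param y Numeric vector of length D (one center entry per domain).
#' @return Non-negative scalar population variance.
#' @export
cross_domain_variance <- function(y) {
  if (length(y) == 0L) stop("'y' must be a non-empty numeric vector")
  y <- as.numeric(y)
  mean((y - mean(y))^2)
}

# internal: per-gene decomposition of the objective.
# Returns, for every gene i, the three components of its selection
# coefficient:
#   recon[i] = (1/2) sum_d || X[i,] - (U V')_i ||^2
#   sep[i]   = sum_d popvar(U^(d)[i, ])          (within-domain separation)
#   agree[i] = sum_j popvar over d of U^(d)[i,j] (cross-domain agreement)
# coefficient[i] = recon[i] - w * sep[i] + alpha * agree[i]
gene_coefficients <- function(dataset, U, V, w, alpha) {
  X <- domain_matrices(dataset)
  D <- length(X)
  m <- n_genes(dataset)
  k <- ncol(U[[1L]])
  check_fit_shapes(dataset, U, V)
  recon <- sep <- numeric(m)
  for (d in seq_len(D)) {
    R <- X[[d]] - tcrossprod(U[[d]], V[[d]])
    recon <- recon + 0.5 * rowSums(R * R)
    Uc <- U[[d]] - rowMeans(U[[d]])
    sep <- sep + rowSums(Uc * Uc) / k
  }
  Ubar <- Reduce(`+`, U) / D
  agree <- numeric(m)
  for (d in seq_len(D)) {
    Dv <- U[[d]] - Ubar
    agree <- agree + rowSums(Dv * Dv)
  }
  agree <- agree / D
  list(reconstruction = recon, separation = sep, agreement = agree,
       coefficient = recon - w * sep + alpha * agree)
}

# internal: consistency checks shared by objective/update functions
check_fit_shapes <- function(dataset, U, V) {
  X <- domain_matrices(dataset)
  D <- length(X)
  m <- n_genes(dataset)
  if (length(U) != D || length(V) != D)
    stop("U and V must have one element per domain (D = ", D, ")")
  k <- ncol(U[[1L]])
  for (d in seq_len(D)) {
    id <- names(dataset$domains)[d]
    if (nrow(U[[d]]) != m || ncol(U[[d]]) != k)
      stop("domain '", id, "': U has dimensions ", nrow(U[[d]]), "x",
           ncol(U[[d]]), "; expected ", m, "x", k)
    if (nrow(V[[d]]) != ncol(X[[d]]) || ncol(V[[d]]) != k)
      stop("domain '", id, "': V has dimensions ", nrow(V[[d]]), "x",
           ncol(V[[d]]), "; expected ", ncol(X[[d]]), "x", k)
  }
  invisible(k)
}

#' Evaluate the multitask clustering objective
#'
#' Computes the scVDMC cost
#' \deqn{\frac12\sum_d \|D_B(X^{(d)} - U^{(d)} V^{(d)\top})\|_F^2
#'       - w \sum_d B^\top \mathrm{Var}(U^{(d)})
#'       + \alpha \sum_{i,j} B_i \mathrm{Var}(Y^{(i,j)}),}
#' where the reconstruction error is measured only on selected genes
#' (`B == 1`), `Var(U^(d))` stacks [row_variance()] over center rows, and
#' `Var(Y^(i,j))` is the [cross_domain_variance()] of one center entry across
#' domains.
#'
#' @param dataset A [multidomain_dataset()].
#' @param U List of D genes x k center matrices.
#' @param V List of D one-hot cells x k assignment matrices.
#' @param B Binary selection vector of length `n_genes(dataset)`.
#' @param w,alpha Non-negative weights of the separation and agreement terms.
#' @return A list with `value` and the diagnostic components
#'   `reconstruction` (already halved), `separation` and `agreement`, so that
#'   `value = reconstruction - w * separation + alpha * agreement`.
#' @export
scvdmc_objective <- function(dataset, U, V, B, w = 0, alpha = 0) {
  B <- check_selection(B, n_genes(dataset))
  parts <- gene_coefficients(dataset, U, V, w, alpha)
  sel <- B == 1
  list(value = sum(parts$coefficient[sel]),
       reconstruction = sum(parts$reconstruction[sel]),
       separation = sum(parts$separation[sel]),
       agreement = sum(parts$agreement[sel]))
}

# internal: validate a binary selection vector
check_selection <- function(B, m) {
  B <- as.numeric(B)
  if (length(B) != m)
    stop("selection vector B has length ", length(B), "; expected ", m)
  if (!all(B %in% c(0, 1))) stop("B must be binary (0/1)")
  B
}
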