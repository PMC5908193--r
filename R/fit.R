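# internal: k-means++ seeding (stats::kmeans has no built-in ++ init).
# points: n x p matrix; returns k x p matrix of initial centers.
kmeanspp_centers <- function(points, k) {
  n <- nrow(points)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(points, 2L, points[idx[1L], ], `-`)^2)
  for (j in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j + 1L] <- sample.int(n, 1L, prob = p)
    nd <- rowSums(sweep(points, 2L, points[idx[j + 1L], ], `-`)^2)
    d2 <- pmin(d2, nd)
  }
  points[idx, , drop = FALSE]
}

# internal: Lloyd k-means with k-means++ seeding and multiple restarts,
# best run by total within-cluster sum of squares. Uses the current RNG
# stream. Returns an integer label vector.
kmeanspp_lloyd <- function(points, k, nstart = 10L, iter_max = 100L) {
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- kmeanspp_centers(points, k)
    centers <- centers + 1e-10 * (seq_len(k) - 1)  # guard duplicate seeds
    km <- suppressWarnings(
      stats::kmeans(points, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best$cluster
}

# internal: pooled k-means initialization of (U, V) for scvdmc.
# Pools all cells (over all genes, or over a screened gene subset),
# clusters once, splits labels per domain, repairs empties, and sets
# centers to per-domain per-cluster means over all genes.
pooled_init <- function(dataset, k, nstart = 10L, screen = NULL) {
  X <- domain_matrices(dataset)
  if (!is.null(screen)) X <- lapply(X, function(x) x[screen, , drop = FALSE])
  pooled <- t(do.call(cbind, X))                 # cells x genes
  labels <- kmeanspp_lloyd(pooled, k, nstart = nstart)
  X <- domain_matrices(dataset)
  splits <- split_by_domain(labels, dataset)
  V <- lapply(seq_along(X), function(d)
    repair_empty_clusters(onehot(splits[[d]], k)))
  U <- lapply(seq_along(X), function(d) {
    counts <- colSums(V[[d]])
    sweep(X[[d]] %*% V[[d]], 2L, counts, `/`)
  })
  list(U = U, V = V)
}

# internal: split a pooled per-cell vector back into per-domain pieces
split_by_domain <- function(x, dataset) {
  ns <- n_cells(dataset)
  ends <- cumsum(ns)
  starts <- ends - ns + 1L
  lapply(seq_along(ns), function(d) x[starts[d]:ends[d]])
}

#' Variance-driven multitask clustering with embedded marker selection
#'
#' Jointly clusters D single-cell populations that share cell types and
#' marker genes. The objective (see [scvdmc_objective()]) combines the
#' k-means reconstruction error restricted to a shared set of `lambda`
#' selected genes, a reward `w` for within-domain cluster-center separation,
#' and a penalty `alpha` on cross-domain disagreement of matched cluster
#' centers. It is minimized by alternating exact block updates: the binary
#' selection vector `B` ([select_features()]), then per domain the one-hot
#' assignments ([update_assignments()], with empty clusters re-populated by
#' [repair_empty_clusters()]) and the closed-form centers
#' ([update_centers()]).
#'
#' Initialization is pooled k-means over all domains and genes with
#' k-means++ seeding, unless `init` supplies starting values. Iterations
#' stop when `B` is unchanged and the relative objective decrease falls
#' below `tol`, or after `max_iter` iterations. The whole run is
#' reproducible given `seed`. A warning is emitted whenever `w` exceeds the
#' Gershgorin positive-semidefiniteness bound for the realized minimum
#' cluster size (see [w_upper_bound_implemented()]).
#'
#' @param dataset A [multidomain_dataset()]; every domain needs at least
#'   `k` cells.
#' @param k Number of clusters (cell types), shared across domains.
#' @param lambda Number of marker genes to select.
#' @param w Weight of the center-separation reward; keep below the PSD
#'   bound.
#' @param alpha Weight of the cross-domain agreement penalty.
#' @param max_iter,tol,seed Solver controls, see [scvdmc_params()].
#' @param init Optional list with elements `U` and `V` (and optionally `B`)
#'   to start from instead of the pooled k-means initialization; forces
#'   `nstart = 1`.
#' @param nstart Number of alternating-minimization restarts; the best run
#'   (PSD-valid partition first, then lowest objective) is returned. Odd
#'   restarts initialize with pooled k-means over all genes; even restarts
#'   use pooled k-means over the most variable genes (variance screening),
#'   which reaches marker-driven solutions that the all-gene pool can miss
#'   when uninformative genes dominate the distances.
#' @param alpha_scaling Passed to [update_centers()].
#' @param keep_history If `TRUE`, per-iteration copies of `V` and `B` are
#'   retained under `$history` (used for diagnostics and equivalence
#'   checks).
#' @return An object of class `scvdmc_fit`: list with per-domain centers
#'   `U`, one-hot assignments `V`, per-domain integer `labels`, selection
#'   vector `B` (with `gene_ids` of the selected markers in `$markers`),
#'   per-gene selection `coefficients`, `objective_trace`, `n_iter`,
#'   `converged`, and the call parameters.
#' @examples
#' sim <- simulate_multidomain(simulation_config(
#'   D = 2, cells_per_domain = c(40, 40), k_true = 3, m_total = 50,
#'   n_markers = 2, seed = 1))
#' fit <- scvdmc(sim$dataset, k = 3, lambda = 2, w = 2, alpha = 1, seed = 1)
#' fit$markers
#' @export
scvdmc <- function(dataset, k, lambda, w = 0, alpha = 0,
                   max_iter = 100L, tol = 1e-6, seed = 1L, init = NULL,
                   nstart = 1L,
                   alpha_scaling = c("derived", "printed"),
                   keep_history = FALSE) {
  alpha_scaling <- match.arg(alpha_scaling)
  stopifnot(inherits(dataset, "multidomain_dataset"))
  params <- scvdmc_params(k, lambda, w, alpha, m = n_genes(dataset),
                          max_iter = max_iter, tol = tol, seed = seed)
  ns <- n_cells(dataset)
  if (any(ns < params$k))
    stop("every domain needs at least k = ", params$k, " cells; domain '",
         names(dataset$domains)[which.min(ns)], "' has ", min(ns))
  nstart <- if (is.null(init)) max(1L, as.integer(nstart)) else 1L
  with_local_seed(params$seed, {
    # across restarts, a solution whose partition keeps w inside the PSD
    # regime beats any out-of-regime solution; ties broken by objective
    best <- NULL
    n_screen <- min(n_genes(dataset), max(50L, 2L * params$lambda))
    for (r in seq_len(nstart)) {
      screen <- if (r %% 2L == 0L)
        as.integer(variance_feature_selection(dataset, n_screen))
      else NULL
      run <- scvdmc_run(dataset, params, init, alpha_scaling, keep_history,
                        screen = screen)
      if (is.null(best) ||
          (run$valid > best$valid) ||
          (run$valid == best$valid && run$objective < best$objective))
        best <- run
    }
    co <- best$coefficients
    res <- structure(
      list(U = best$U, V = best$V,
           labels = lapply(best$V, hard_labels),
           B = best$B,
           markers = dataset$gene_ids[best$B == 1],
           coefficients = stats::setNames(co, dataset$gene_ids),
           objective_trace = best$trace,
           n_iter = best$n_iter,
           converged = best$converged,
           params = params,
           history = best$history),
      class = "scvdmc_fit")
    names(res$labels) <- names(dataset$domains)
    res
  })
}

# internal: one alternating-minimization run from one initialization.
# Returns the best iterate visited, preferring iterates whose partition
# keeps w below the realized PSD bound (the regime where every center
# update is a well-posed minimization); under monotone descent that is the
# final iterate, and it guards against oscillation when the empty-cluster
# splitting perturbs the trajectory or an aggressive w rewards degenerate
# partitions with near-singleton clusters.
scvdmc_run <- function(dataset, params, init, alpha_scaling, keep_history,
                       screen = NULL) {
  D <- n_domains(dataset)
  if (is.null(init)) {
    st <- pooled_init(dataset, params$k, screen = screen)
  } else {
    st <- list(U = init$U, V = init$V)
    check_fit_shapes(dataset, st$U, st$V)
  }
  U <- st$U; V <- st$V
  B_prev <- NULL
  obj_prev <- Inf
  trace <- numeric(0)
  history <- if (keep_history) list() else NULL
  warned_w <- FALSE
  converged <- FALSE
  best <- NULL
  it <- 0L
  while (it < params$max_iter) {
    it <- it + 1L
    B <- select_features(dataset, U, V, params$w, params$alpha,
                         params$lambda)
    iter_valid <- TRUE
    for (d in seq_len(D)) {
      Vd <- update_assignments(dataset$domains[[d]], U[[d]], B)
      V[[d]] <- repair_empty_clusters(Vd)
      c_min <- min(colSums(V[[d]]))
      bnd <- w_upper_bound_implemented(params$k, D, params$alpha, c_min)
      if (params$w > bnd) iter_valid <- FALSE
      # keep the center subproblem strictly convex for the partition at
      # hand: a w beyond the realized bound would make the update a saddle
      # and let center separation run away on a degenerate partition
      w_eff <- min(params$w, 0.95 * bnd)
      if (!warned_w && params$w > bnd) {
        warning("w = ", params$w, " exceeds the PSD bound ",
                signif(bnd, 6),
                " for the realized minimum cluster size ", c_min,
                "; the center-update weight is clamped to ",
                signif(w_eff, 6), call. = FALSE)
        warned_w <- TRUE
      }
      U[[d]] <- update_centers(d, dataset, V, U, B, w_eff, params$alpha,
                               alpha_scaling = alpha_scaling)
    }
    obj <- scvdmc_objective(dataset, U, V, B, params$w, params$alpha)$value
    if (!is.finite(obj))
      stop("objective is not finite at iteration ", it,
           "; check the input values and hyperparameters")
    trace <- c(trace, obj)
    if (keep_history)
      history[[it]] <- list(B = as.numeric(B), V = V)
    if (is.null(best) ||
        (iter_valid > best$valid) ||
        (iter_valid == best$valid && obj < best$objective))
      best <- list(U = U, V = V, B = as.numeric(B),
                   coefficients = attr(B, "coefficients"),
                   objective = obj, valid = iter_valid)
    rel <- abs(obj_prev - obj) / max(1, abs(obj_prev))
    if (!is.null(B_prev) && identical(as.numeric(B), B_prev) &&
        rel < params$tol) {
      converged <- TRUE
      break
    }
    B_prev <- as.numeric(B)
    obj_prev <- obj
  }
  c(best, list(trace = trace, n_iter = it, converged = converged,
               history = history))
}

#' @export
print.scvdmc_fit <- function(x, ...) {
  cat("<scvdmc_fit> k = ", x$params$k, ", lambda = ", x$params$lambda,
      ", w = ", x$params$w, ", alpha = ", x$params$alpha, "\n",
      "  ", length(x$U), " domain(s), ", x$n_iter, " iteration(s), ",
      if (x$converged) "converged" else "not converged", "\n",
      "  final objective: ", signif(utils::tail(x$objective_trace, 1), 8),
      "\n", "  markers: ",
      paste(utils::head(x$markers, 8), collapse = ", "),
      if (length(x$markers) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
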