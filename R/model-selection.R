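#' Upper bounds on the center-separation weight w
#'
#' The center subproblem has a unique minimizer only while its k x k Hessian
#' \deqn{H = V^\top V - \frac{2w}{k}\Psi + \frac{2\alpha}{D}\Phi_{dd} I_k}
#' stays positive semi-definite. By the Gershgorin circle theorem, diagonal
#' dominance with non-negative diagonal suffices, which yields an upper
#' bound on `w` in terms of the smallest cluster size `c_min`.
#'
#' `w_upper_bound_printed()` evaluates the originally printed closed form
#' \deqn{w \le \frac{k^2 c_{min}}{4(k-1)} +
#'       \frac{\alpha k^3 (D-1)}{2 D^2 (k-1)},}
#' whose agreement term carries a factor k inherited from the printed
#' closed-form center update. `w_upper_bound_implemented()` is the same
#' derivation carried out on the Hessian of the objective as implemented
#' (agreement diagonal `2 alpha (D-1)/D^2`, i.e. k^2 instead of k^3 in the
#' second term); it is the bound the solver warns against. Setting
#' `c_min = 1` (the default) gives the loose bound valid for any non-empty
#' clustering.
#'
#' @param k Number of clusters, at least 2.
#' @param D Number of domains, at least 1.
#' @param alpha Non-negative agreement weight.
#' @param c_min Smallest admissible cluster size, at least 1.
#' @return Positive scalar bound on `w`.
#' @export
w_upper_bound_printed <- function(k, D, alpha = 0, c_min = 1) {
  check_bound_args(k, D, alpha, c_min)
  k^2 * c_min / (4 * (k - 1)) +
    alpha * k^3 * (D - 1) / (2 * D^2 * (k - 1))
}

#' @rdname w_upper_bound_printed
#' @export
w_upper_bound_implemented <- function(k, D, alpha = 0, c_min = 1) {
  check_bound_args(k, D, alpha, c_min)
  # H_ii - sum_{j != i} |H_ij| = c_i - 4w(k-1)/k^2 + 2 alpha (D-1)/D^2 >= 0
  k^2 * c_min / (4 * (k - 1)) +
    alpha * k^2 * (D - 1) / (2 * D^2 * (k - 1))
}

check_bound_args <- function(k, D, alpha, c_min) {
  if (k < 2) stop("'k' must be at least 2")
  if (D < 1) stop("'D' must be at least 1")
  if (alpha < 0) stop("'alpha' must be non-negative")
  if (c_min < 1) stop("'c_min' must be at least 1")
  invisible(TRUE)
}

# internal: the implemented center-subproblem Hessian for given cluster sizes
center_hessian <- function(counts, D, w, alpha) {
  k <- length(counts)
  Psi <- diag(k) - matrix(1 / k, k, k)
  phi_dd <- if (D > 1) (1 - 1 / D) else 0
  diag(counts, k) - (2 * w / k) * Psi + (2 * alpha / D) * phi_dd * diag(k)
}

#' Suggest a center-separation weight
#'
#' Returns `frac` times the implemented PSD bound evaluated at
#' `c_min = 2`, the smallest non-degenerate cluster size. The resulting
#' weight sits above the loose (`c_min = 1`) bound and below the
#' `c_min = 2` bound: every center update on a partition free of singleton
#' clusters remains a well-posed minimization, while partitions containing
#' singleton clusters fall outside the PSD regime and are disfavored by the
#' solver — singletons are the degenerate configurations through which an
#' aggressive separation reward would otherwise manufacture center
#' variance.
#'
#' @inheritParams scvdmc
#' @param frac Fraction of the `c_min = 2` bound to use (default 0.75).
#' @param c_min Smallest cluster size assumed non-degenerate (default 2).
#' @return Positive scalar suggested value for `w`.
#' @export
suggest_w <- function(dataset, k, alpha = 0, frac = 0.75, c_min = 2) {
  frac * w_upper_bound_implemented(k, n_domains(dataset), alpha, c_min)
}

#' Within-clusters sum of squares on the selected genes
#'
#' The elbow statistic for choosing k:
#' \deqn{T_s = \sum_d \|D_B (X^{(d)} - U^{(d)} V^{(d)\top})\|_F^2,}
#' i.e. twice the (halved) reconstruction term of the objective, restricted
#' to the selected marker genes.
#'
#' @param dataset A [multidomain_dataset()].
#' @param result A [scvdmc()] fit on that dataset.
#' @return Non-negative scalar.
#' @export
elbow_statistic <- function(dataset, result) {
  obj <- scvdmc_objective(dataset, result$U, result$V, result$B)
  2 * obj$reconstruction
}

#' Scan the number of clusters with the elbow statistic
#'
#' Fits the model at each candidate `k` over several seeds and reports the
#' mean within-clusters sum of squares [elbow_statistic()] per `k`; the best
#' `k` sits at the "elbow" (maximum curvature) of the resulting curve.
#' Repeats default to 10.
#'
#' @inheritParams scvdmc
#' @param k_values Integer vector of candidate cluster counts (each >= 2 and
#'   at most the smallest domain size).
#' @param repeats Number of repeated fits per `k` (different seeds).
#' @return A data frame of class `elbow_scan` with columns `k`, `mean_ts`,
#'   and the per-repeat values as attribute `"repeats"` (long data frame
#'   with columns `k`, `repeat`, `ts`).
#' @export
elbow_scan <- function(dataset, k_values, lambda, w = 0, alpha = 0,
                       repeats = 10L, max_iter = 100L, tol = 1e-6,
                       seed = 1L, ...) {
  k_values <- as.integer(k_values)
  if (any(k_values < 2L)) stop("all k_values must be at least 2")
  if (any(k_values > min(n_cells(dataset))))
    stop("k_values cannot exceed the smallest domain size")
  rows <- list()
  for (k in k_values) {
    for (r in seq_len(repeats)) {
      fit <- scvdmc(dataset, k = k, lambda = lambda, w = w, alpha = alpha,
                    max_iter = max_iter, tol = tol,
                    seed = seed + 1000L * (r - 1L), ...)
      rows[[length(rows) + 1L]] <-
        data.frame(k = k, rep = r, ts = elbow_statistic(dataset, fit))
    }
  }
  long <- do.call(rbind, rows)
  means <- stats::aggregate(ts ~ k, data = long, FUN = mean)
  out <- data.frame(k = means$k, mean_ts = means$ts)
  attr(out, "repeats") <- long
  class(out) <- c("elbow_scan", "data.frame")
  out
}

#' Total cross-domain disagreement of matched cluster centers
#'
#' Diagnostic used to tune `alpha`: the sum, over cluster indices j and
#' unordered domain pairs (d, l), of the Euclidean distance between the
#' j-th center of domain d and the j-th center of domain l, restricted to
#' the selected genes. Clusters are matched by shared column index, the
#' alignment induced by the agreement coupling and the common
#' initialization. Increasing `alpha` should drive this diagnostic down
#' until it plateaus; pick the smallest `alpha` near the plateau.
#'
#' @param result A [scvdmc()] fit with at least two domains.
#' @return Non-negative scalar.
#' @export
alpha_diagnostic <- function(result) {
  D <- length(result$U)
  if (D < 2) stop("the agreement diagnostic requires at least two domains")
  sel <- result$B == 1
  total <- 0
  for (d in seq_len(D - 1)) {
    for (l in (d + 1):D) {
      diff <- result$U[[d]][sel, , drop = FALSE] -
        result$U[[l]][sel, , drop = FALSE]
      total <- total + sum(sqrt(colSums(diff^2)))
    }
  }
  total
}

#' Scan the agreement weight alpha
#'
#' Fits the model over a grid of `alpha` values (default mirroring the
#' values used in practice: 0, 0.5, 1, 2, 5, 10, 20), averaging
#' [alpha_diagnostic()] over `repeats` seeds per value, and suggests the
#' smallest `alpha` whose mean diagnostic is within `plateau_tol` (default
#' 10%) of the plateau (the minimum mean over the grid).
#'
#' @inheritParams scvdmc
#' @param alpha_values Numeric grid of candidate agreement weights.
#' @param repeats Number of repeated fits per value.
#' @param plateau_tol Relative closeness to the plateau that counts as
#'   "not changing much".
#' @return A data frame of class `alpha_scan` with columns `alpha` and
#'   `mean_diagnostic`; the suggested value is attribute `"suggested"`, the
#'   per-repeat values attribute `"repeats"`.
#' @export
alpha_scan <- function(dataset, k, lambda, w = 0,
                       alpha_values = c(0, 0.5, 1, 2, 5, 10, 20),
                       repeats = 10L, plateau_tol = 0.1,
                       max_iter = 100L, tol = 1e-6, seed = 1L, ...) {
  rows <- list()
  for (a in alpha_values) {
    for (r in seq_len(repeats)) {
      fit <- scvdmc(dataset, k = k, lambda = lambda, w = w, alpha = a,
                    max_iter = max_iter, tol = tol,
                    seed = seed + 1000L * (r - 1L), ...)
      rows[[length(rows) + 1L]] <-
        data.frame(alpha = a, rep = r, diagnostic = alpha_diagnostic(fit))
    }
  }
  long <- do.call(rbind, rows)
  means <- stats::aggregate(diagnostic ~ alpha, data = long, FUN = mean)
  out <- data.frame(alpha = means$alpha, mean_diagnostic = means$diagnostic)
  plateau <- min(out$mean_diagnostic)
  ok <- out$mean_diagnostic <= plateau * (1 + plateau_tol)
  attr(out, "suggested") <- min(out$alpha[ok])
  attr(out, "repeats") <- long
  class(out) <- c("alpha_scan", "data.frame")
  out
}
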