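#' Variance-based gene selection
#'
#' Baseline feature selection: ranks genes by their pooled across-cell
#' variance (all domains concatenated) and returns the `lambda` most
#' variable gene indices, ties to the lowest index.
#'
#' @param dataset A [multidomain_dataset()].
#' @param lambda Number of genes to select.
#' @return Integer vector of `lambda` gene indices (attribute `"gene_ids"`
#'   carries the identifiers).
#' @export
variance_feature_selection <- function(dataset, lambda) {
  m <- n_genes(dataset)
  lambda <- as.integer(lambda)
  if (lambda < 1L || lambda > m)
    stop("'lambda' must be in [1, ", m, "]")
  pooled <- do.call(cbind, domain_matrices(dataset))
  v <- rowMeans((pooled - rowMeans(pooled))^2)
  idx <- order(v, decreasing = TRUE)[seq_len(lambda)]
  structure(idx, gene_ids = dataset$gene_ids[idx])
}

#' Pooled and separated k-means baselines
#'
#' `pooled_kmeans()` concatenates the cells of all domains and runs k-means
#' (k-means++ seeding, Lloyd iterations, best of `nstart` restarts by total
#' within-cluster sum of squares) once on the pool, then splits the labels
#' back per domain, so clusters share one labeling across domains.
#' `separated_kmeans()` clusters each domain independently with the same
#' procedure; its labels are not aligned across domains.
#'
#' @param dataset A [multidomain_dataset()].
#' @param k Number of clusters.
#' @param gene_subset Optional integer or character vector restricting the
#'   clustering to a gene subset (e.g. from
#'   [variance_feature_selection()]).
#' @param seed Integer seed.
#' @param nstart Number of restarts.
#' @return A named list (one element per domain) of integer label vectors
#'   in `1..k`.
#' @export
pooled_kmeans <- function(dataset, k, gene_subset = NULL, seed = 1L,
                          nstart = 10L) {
  X <- subset_genes(dataset, gene_subset)
  pooled <- t(do.call(cbind, X))
  if (nrow(pooled) < k) stop("fewer cells than clusters")
  labels <- with_local_seed(seed, kmeanspp_lloyd(pooled, k, nstart = nstart))
  out <- split_by_domain(labels, dataset)
  names(out) <- names(dataset$domains)
  out
}

#' @rdname pooled_kmeans
#' @export
separated_kmeans <- function(dataset, k, gene_subset = NULL, seed = 1L,
                             nstart = 10L) {
  X <- subset_genes(dataset, gene_subset)
  out <- with_local_seed(seed, lapply(X, function(x) {
    if (ncol(x) < k) stop("fewer cells than clusters in one domain")
    kmeanspp_lloyd(t(x), k, nstart = nstart)
  }))
  names(out) <- names(dataset$domains)
  out
}

# internal: gene-subset the domain matrices
subset_genes <- function(dataset, gene_subset) {
  X <- domain_matrices(dataset)
  if (is.null(gene_subset)) return(X)
  if (is.character(gene_subset))
    gene_subset <- match(gene_subset, dataset$gene_ids)
  if (anyNA(gene_subset)) stop("unknown gene identifiers in 'gene_subset'")
  lapply(X, function(x) x[gene_subset, , drop = FALSE])
}

#' Best one-to-one matching clustering error
#'
#' The misclassification fraction after optimally pairing predicted
#' clusters with true clusters: an optimal assignment on the confusion
#' matrix (maximum-weight bipartite matching, equivalent to the Hungarian
#' method) maximizes the matched cell count; the error is the fraction left
#' unmatched. The measure is symmetric and invariant under independent
#' relabeling of either side; when the two sides have different numbers of
#' clusters, unmatched clusters count fully as errors.
#'
#' @param pred,truth Integer (or factor) label vectors of equal length.
#' @return Error fraction in `[0, 1]`.
#' @export
clustering_error <- function(pred, truth) {
  pred <- as.integer(as.factor(pred))
  truth <- as.integer(as.factor(truth))
  if (length(pred) != length(truth))
    stop("label vectors differ in length (", length(pred), " vs ",
         length(truth), ")")
  n <- length(pred)
  tab <- table(pred, truth)
  r <- nrow(tab); s <- ncol(tab)
  # bipartite graph: predicted clusters 1..r, true clusters r+1..r+s,
  # edges weighted by confusion counts
  edges <- which(tab > 0, arr.ind = TRUE)
  if (nrow(edges) == 0) return(1)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, r), rep(TRUE, s)),
    edges = as.vector(t(cbind(edges[, 1L], r + edges[, 2L]))))
  igraph::E(g)$weight <- tab[edges]
  matched <- igraph::max_bipartite_match(g)$matching_weight
  1 - matched / n
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions
#' computed from the contingency table: 1 for identical partitions, 0 in
#' expectation for independent ones.
#'
#' @param pred,truth Label vectors of equal length (at least 2 cells).
#' @return Scalar ARI, at most 1.
#' @export
adjusted_rand_index <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("label vectors differ in length (", length(pred), " vs ",
         length(truth), ")")
  if (length(pred) < 2L) stop("at least two cells are required")
  mclust::adjustedRandIndex(pred, truth)
}

#' Evaluate a clustering against ground truth
#'
#' Convenience report combining, per domain and pooled, the best-matching
#' [clustering_error()] and [adjusted_rand_index()]. The pooled error is
#' computed with one global cluster matching (all domains concatenated);
#' per-domain errors re-match within each domain.
#'
#' @param labels Named list of predicted per-domain integer label vectors.
#' @param truth_labels Named list of true per-domain label vectors.
#' @return A data frame with columns `domain`, `n`, `error`, `ari`; the
#'   last row (`domain == "pooled"`) uses the global matching.
#' @export
evaluate_clustering <- function(labels, truth_labels) {
  stopifnot(length(labels) == length(truth_labels))
  rows <- lapply(seq_along(labels), function(d) {
    data.frame(domain = names(labels)[d] %||% paste0("domain_", d),
               n = length(labels[[d]]),
               error = clustering_error(labels[[d]], truth_labels[[d]]),
               ari = adjusted_rand_index(labels[[d]], truth_labels[[d]]))
  })
  all_pred <- unlist(labels, use.names = FALSE)
  all_true <- unlist(truth_labels, use.names = FALSE)
  rows[[length(rows) + 1L]] <-
    data.frame(domain = "pooled", n = length(all_pred),
               error = clustering_error(all_pred, all_true),
               ari = adjusted_rand_index(all_pred, all_true))
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
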