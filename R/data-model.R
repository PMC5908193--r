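#' Construct a single-population expression domain
#'
#' An expression domain holds one single-cell population as a genes x cells
#' matrix of non-negative, typically log-transformed expression values
#' (e.g. log2(FPKM + 1) or log2(UMI + 1)).
#'
#' @param values Numeric matrix, genes in rows, cells in columns. All entries
#'   must be finite. Row names, if present, are taken as gene identifiers.
#' @param domain_id Character scalar naming the population (replicate, donor,
#'   patient sample).
#' @param cell_ids Character vector of unique cell identifiers, one per
#'   column. Defaults to the column names of `values`, or `cell_1 ...` when
#'   absent.
#' @return An object of class `expression_domain`: a list with elements
#'   `domain_id`, `values` and `cell_ids`.
#' @seealso [multidomain_dataset()]
#' @export
expression_domain <- function(values, domain_id, cell_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 1L)
    stop("domain '", domain_id, "': at least one cell is required")
  if (!all(is.finite(values)))
    stop("domain '", domain_id, "': expression values must be finite")
  if (is.null(cell_ids)) {
    cell_ids <- colnames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(values)))
  }
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != ncol(values))
    stop("domain '", domain_id, "': cell_ids length (", length(cell_ids),
         ") does not match the number of columns (", ncol(values), ")")
  if (anyDuplicated(cell_ids))
    stop("domain '", domain_id, "': cell_ids must be unique")
  colnames(values) <- cell_ids
  structure(
    list(domain_id = as.character(domain_id)[1L],
         values = values,
         cell_ids = cell_ids),
    class = "expression_domain"
  )
}

#' @export
print.expression_domain <- function(x, ...) {
  cat("<expression_domain> ", x$domain_id, ": ",
      nrow(x$values), " genes x ", ncol(x$values), " cells\n", sep = "")
  invisible(x)
}

#' Bundle several expression domains over a shared gene index
#'
#' All domains must carry exactly the same genes in the same order; use
#' [align_gene_index()] to intersect and reorder heterogeneous inputs first.
#'
#' @param domains List of [expression_domain()] objects.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to the row names of the first domain.
#' @return An object of class `multidomain_dataset`: a list with `gene_ids`
#'   and `domains`.
#' @export
multidomain_dataset <- function(domains, gene_ids = NULL) {
  if (inherits(domains, "expression_domain")) domains <- list(domains)
  if (length(domains) < 1L) stop("at least one domain is required")
  if (!all(vapply(domains, inherits, logical(1), "expression_domain")))
    stop("'domains' must be a list of expression_domain objects")
  m <- nrow(domains[[1L]]$values)
  if (m < 2L) stop("at least two genes are required")
  if (is.null(gene_ids)) gene_ids <- rownames(domains[[1L]]$values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(m))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != m)
    stop("gene_ids length (", length(gene_ids),
         ") does not match the number of genes (", m, ")")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  for (d in domains) {
    if (nrow(d$values) != m)
      stop("domain '", d$domain_id, "' has ", nrow(d$values),
           " genes; expected ", m)
  }
  domains <- lapply(domains, function(d) {
    rownames(d$values) <- gene_ids
    d
  })
  ids <- vapply(domains, `[[`, character(1), "domain_id")
  if (anyDuplicated(ids)) stop("domain_id values must be unique")
  names(domains) <- ids
  structure(list(gene_ids = gene_ids, domains = domains),
            class = "multidomain_dataset")
}

#' @export
print.multidomain_dataset <- function(x, ...) {
  ns <- vapply(x$domains, function(d) ncol(d$values), integer(1))
  cat("<multidomain_dataset> ", length(x$gene_ids), " genes, ",
      length(x$domains), " domain(s): ",
      paste0(names(x$domains), " (n=", ns, ")", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Number of domains, genes and cells
#'
#' @param dataset A [multidomain_dataset()].
#' @return `n_domains()` and `n_genes()` return integers; `n_cells()` returns
#'   an integer vector with one entry per domain.
#' @export
n_domains <- function(dataset) length(dataset$domains)

#' @rdname n_domains
#' @export
n_genes <- function(dataset) length(dataset$gene_ids)

#' @rdname n_domains
#' @export
n_cells <- function(dataset)
  vapply(dataset$domains, function(d) ncol(d$values), integer(1))

# internal: list of expression matrices
domain_matrices <- function(dataset) lapply(dataset$domains, `[[`, "values")

#' Validate scVDMC hyperparameters
#'
#' Checks the admissible ranges of the solver hyperparameters: `k >= 2`
#' clusters, `1 <= lambda <= m` selected marker genes, non-negative weights
#' `w` (within-domain center separation) and `alpha` (cross-domain center
#' agreement), and the solver controls.
#'
#' @param k Integer, number of clusters (cell types), at least 2.
#' @param lambda Integer, number of marker genes to select, in `[1, m]`.
#' @param w Non-negative real, weight of the center-separation reward.
#' @param alpha Non-negative real, weight of the cross-domain agreement
#'   penalty.
#' @param m Number of genes the parameters will be applied to.
#' @param max_iter Positive integer iteration cap.
#' @param tol Positive relative objective-change convergence threshold.
#' @param seed Integer seed driving initialization and empty-cluster splits.
#' @return A validated list of class `scvdmc_params` (invisibly usable as a
#'   plain list).
#' @export
scvdmc_params <- function(k, lambda, w = 0, alpha = 0, m = NULL,
                          max_iter = 100L, tol = 1e-6, seed = 1L) {
  k <- as.integer(k)
  lambda <- as.integer(lambda)
  if (is.na(k) || k < 2L) stop("'k' must be an integer >= 2")
  if (is.na(lambda) || lambda < 1L) stop("'lambda' must be an integer >= 1")
  if (!is.null(m) && lambda > m)
    stop("'lambda' (", lambda, ") exceeds the number of genes (", m, ")")
  if (!is.finite(w) || w < 0) stop("'w' must be a non-negative real")
  if (!is.finite(alpha) || alpha < 0)
    stop("'alpha' must be a non-negative real")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("'max_iter' must be >= 1")
  if (!is.finite(tol) || tol <= 0) stop("'tol' must be > 0")
  structure(list(k = k, lambda = lambda, w = w, alpha = alpha,
                 max_iter = max_iter, tol = tol, seed = as.integer(seed)),
            class = "scvdmc_params")
}

# internal: run expr with a locally-seeded RNG stream, restoring global state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
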