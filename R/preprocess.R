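# internal: build a filter log entry
filter_log <- function(step, removed, n_before, n_after) {
  stopifnot(n_before - n_after == length(removed))
  structure(list(step = step, removed = removed,
                 n_before = n_before, n_after = n_after),
            class = "filter_log")
}

#' @export
print.filter_log <- function(x, ...) {
  cat("<filter_log> ", x$step, ": ", x$n_before, " -> ", x$n_after,
      " (", length(x$removed), " removed)\n", sep = "")
  invisible(x)
}

# internal: drop genes by logical keep mask, preserving order
drop_genes <- function(dataset, keep, step) {
  removed <- dataset$gene_ids[!keep]
  doms <- lapply(dataset$domains, function(d) {
    d$values <- d$values[keep, , drop = FALSE]
    d
  })
  list(dataset = multidomain_dataset(doms,
                                     gene_ids = dataset$gene_ids[keep]),
       log = filter_log(step, removed, length(keep), sum(keep)))
}

#' Log-transform expression values
#'
#' Applies `log_base(x + pseudocount)` elementwise, the standard
#' variance-stabilizing transform for FPKM/UMI matrices (default
#' `log2(x + 1)`).
#'
#' @param dataset A [multidomain_dataset()] of non-negative values.
#' @param pseudocount Value added before taking logs (avoids zeros).
#' @param base Logarithm base.
#' @return The transformed dataset.
#' @export
log_transform <- function(dataset, pseudocount = 1, base = 2) {
  doms <- lapply(dataset$domains, function(d) {
    if (any(d$values < 0))
      stop("domain '", d$domain_id,
           "': negative values cannot be log-transformed")
    d$values <- log(d$values + pseudocount, base = base)
    d
  })
  multidomain_dataset(doms, gene_ids = dataset$gene_ids)
}

#' Remove lowly expressed genes
#'
#' Drops genes whose mean expression over all cells pooled across domains
#' is below `threshold` (strictly; a gene at exactly the threshold is
#' kept). Intended for log-transformed values, e.g. mean log2(FPKM) < 1.5.
#'
#' @param dataset A [multidomain_dataset()], already log-transformed.
#' @param threshold Strict lower bound on the pooled mean.
#' @return A list with the filtered `dataset` and a `log` (class
#'   `filter_log`).
#' @export
filter_low_expression_genes <- function(dataset, threshold = 1.5) {
  pooled <- do.call(cbind, domain_matrices(dataset))
  drop_genes(dataset, rowMeans(pooled) >= threshold,
             step = paste0("low_expression_genes(mean<", threshold, ")"))
}

#' Remove cells expressing too few genes
#'
#' Drops cells with fewer than `min_genes` genes at a strictly positive
#' value; a cell with exactly `min_genes` expressed genes is kept.
#'
#' @param dataset A [multidomain_dataset()].
#' @param min_genes Minimum number of expressed (value > 0) genes.
#' @return A list with the filtered `dataset` and a `log`.
#' @export
filter_cells_min_genes <- function(dataset, min_genes = 2000) {
  removed <- character(0)
  doms <- lapply(dataset$domains, function(d) {
    keep <- colSums(d$values > 0) >= min_genes
    removed <<- c(removed, d$cell_ids[!keep])
    if (!any(keep))
      stop("domain '", d$domain_id, "': no cells pass the filter")
    expression_domain(d$values[, keep, drop = FALSE], d$domain_id,
                      cell_ids = d$cell_ids[keep])
  })
  n_before <- sum(n_cells(dataset))
  ds <- multidomain_dataset(doms, gene_ids = dataset$gene_ids)
  list(dataset = ds,
       log = filter_log(paste0("cells_min_genes(>=", min_genes, ")"),
                        removed, n_before, sum(n_cells(ds))))
}

#' Remove genes expressed uniformly within any single domain
#'
#' Drops genes that are constant (zero variance) within at least one
#' domain; such genes cannot separate clusters there and break
#' variance-based terms.
#'
#' @param dataset A [multidomain_dataset()].
#' @return A list with the filtered `dataset` and a `log`.
#' @export
filter_uniform_genes <- function(dataset) {
  uniform <- Reduce(`|`, lapply(domain_matrices(dataset), function(x) {
    if (ncol(x) == 1L) rep(TRUE, nrow(x))
    else rowSums((x - rowMeans(x))^2) == 0
  }))
  drop_genes(dataset, !uniform, step = "uniform_within_domain_genes")
}

#' Remove genes detected in too few cells
#'
#' Drops genes with a strictly positive value in fewer than `min_cells`
#' cells pooled across domains; a gene detected in exactly `min_cells`
#' cells is kept.
#'
#' @param dataset A [multidomain_dataset()].
#' @param min_cells Minimum number of cells a gene must be detected in.
#' @return A list with the filtered `dataset` and a `log`.
#' @export
filter_genes_min_cells <- function(dataset, min_cells = 3) {
  pooled <- do.call(cbind, domain_matrices(dataset))
  drop_genes(dataset, rowSums(pooled > 0) >= min_cells,
             step = paste0("genes_min_cells(>=", min_cells, ")"))
}

#' Iteratively exclude confounding genes from the selection
#'
#' Fits the multitask clustering model; if any of the top `top_n` ranked
#' selected markers (ascending selection coefficient) belong to the
#' exclusion list (e.g. cell-cycle genes), removes those genes from the
#' dataset and refits, repeating until no excluded gene is selected or
#' `max_rounds` is reached.
#'
#' @param dataset A [multidomain_dataset()].
#' @param exclusion_list Character vector of gene identifiers to keep out
#'   of the selection (e.g. cell-cycle genes).
#' @param top_n Number of top-ranked markers screened per round.
#' @param max_rounds Cap on the number of refits.
#' @param ... Passed to [scvdmc()] (`k`, `lambda`, `w`, `alpha`, `seed`,
#'   ...).
#' @return A list with the final `fit`, the reduced `dataset`, the
#'   `removed` gene identifiers, and the number of `rounds` used.
#' @export
exclude_genes_iterative <- function(dataset, exclusion_list, top_n = 100,
                                    max_rounds = 10L, ...) {
  exclusion_list <- as.character(exclusion_list)
  removed <- character(0)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    fit <- scvdmc(dataset, ...)
    sel <- fit$markers
    ranked <- sel[order(fit$coefficients[sel])]
    hits <- intersect(utils::head(ranked, top_n), exclusion_list)
    if (length(hits) == 0L || rounds >= max_rounds) break
    keep <- !(dataset$gene_ids %in% hits)
    dataset <- drop_genes(dataset, keep, "exclusion_list")$dataset
    removed <- c(removed, hits)
  }
  list(fit = fit, dataset = dataset, removed = removed, rounds = rounds)
}

#' Serialize filter logs to TSV
#'
#' @param logs A `filter_log` or list of them.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_filter_log <- function(logs, path) {
  if (inherits(logs, "filter_log")) logs <- list(logs)
  rows <- lapply(logs, function(l) {
    data.frame(step = l$step,
               n_before = l$n_before, n_after = l$n_after,
               removed = if (length(l$removed))
                 paste(l$removed, collapse = ",") else "")
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
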