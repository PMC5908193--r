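#' Read one expression domain from disk
#'
#' Supports two plain-text layouts: a dense TSV with a header row of cell
#' identifiers and gene identifiers in the first column, or a MatrixMarket
#' coordinate file with 10x-style gene and barcode sidecar files (one
#' identifier per line). MatrixMarket files following the 10x convention
#' store genes as rows; set `transpose = TRUE` for cells-as-rows files.
#'
#' @param path Path to the matrix file (`.tsv` or `.mtx`).
#' @param format `"dense-tsv"` or `"matrixmarket"`.
#' @param domain_id Domain name; defaults to the file base name.
#' @param genes_file,barcodes_file Sidecar paths for the MatrixMarket
#'   layout; default to `genes.tsv` / `barcodes.tsv` next to `path`.
#' @param transpose Transpose a MatrixMarket matrix stored cells x genes.
#' @return An [expression_domain()] with gene identifiers as row names.
#' @export
read_domain <- function(path, format = c("dense-tsv", "matrixmarket"),
                        domain_id = NULL, genes_file = NULL,
                        barcodes_file = NULL, transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(domain_id))
    domain_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "dense-tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
      stop("malformed dense TSV (need gene-id column plus >= 1 cell): ",
           path)
    gene_ids <- as.character(df[[1L]])
    mat <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    if (anyDuplicated(gene_ids))
      stop("duplicate gene identifiers in ", path)
    rownames(mat) <- gene_ids
    return(expression_domain(mat, domain_id = domain_id,
                             cell_ids = colnames(df)[-1L]))
  }
  # MatrixMarket triplet + sidecars
  dir <- dirname(path)
  if (is.null(genes_file)) genes_file <- file.path(dir, "genes.tsv")
  if (is.null(barcodes_file)) barcodes_file <- file.path(dir, "barcodes.tsv")
  mat <- tryCatch(as.matrix(Matrix::readMM(path)), error = function(e)
    stop("malformed MatrixMarket file ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (transpose) mat <- t(mat)
  genes <- read_id_column(genes_file)
  barcodes <- read_id_column(barcodes_file)
  if (length(genes) != nrow(mat))
    stop("gene sidecar ", genes_file, " has ", length(genes),
         " rows but the matrix has ", nrow(mat), " genes")
  if (length(barcodes) != ncol(mat))
    stop("barcode sidecar ", barcodes_file, " has ", length(barcodes),
         " rows but the matrix has ", ncol(mat), " cells")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in ", genes_file)
  rownames(mat) <- genes
  expression_domain(mat, domain_id = domain_id, cell_ids = barcodes)
}

# internal: first tab-separated column of a sidecar file
read_id_column <- function(path) {
  if (!file.exists(path)) stop("sidecar file not found: ", path)
  vapply(strsplit(readLines(path), "\t", fixed = TRUE), `[[`, character(1),
         1L)
}

#' Write one expression domain to disk
#'
#' Inverse of [read_domain()]: emits either `<base>.tsv` (dense, 17
#' significant digits, lossless for doubles) or `<base>.mtx` with
#' `<base>.genes.tsv` / `<base>.barcodes.tsv` sidecars.
#'
#' @param domain An [expression_domain()].
#' @param base Output path without extension.
#' @param format `"dense-tsv"` or `"matrixmarket"`.
#' @param gene_ids Gene identifiers; default row names.
#' @return The files written, invisibly.
#' @export
write_domain <- function(domain, base, format = c("dense-tsv",
                                                  "matrixmarket"),
                         gene_ids = rownames(domain$values)) {
  format <- match.arg(format)
  if (is.null(gene_ids))
    gene_ids <- paste0("gene_", seq_len(nrow(domain$values)))
  if (format == "dense-tsv") {
    path <- paste0(base, ".tsv")
    df <- data.frame(gene_id = gene_ids,
                     signif17(domain$values), check.names = FALSE)
    colnames(df) <- c("gene_id", domain$cell_ids)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  mtx <- paste0(base, ".mtx")
  gf <- paste0(base, ".genes.tsv")
  bf <- paste0(base, ".barcodes.tsv")
  Matrix::writeMM(Matrix::Matrix(domain$values, sparse = TRUE), mtx)
  writeLines(gene_ids, gf)
  writeLines(domain$cell_ids, bf)
  invisible(c(mtx, gf, bf))
}

# internal: format numbers at 17 significant digits (round-trip safe);
# kept as character so the writer does not re-round
signif17 <- function(x) {
  out <- apply(x, 2L, function(col) sprintf("%.17g", col))
  matrix(out, nrow(x), ncol(x))
}

#' Align several domains onto a shared gene index
#'
#' Intersects the gene identifiers (row names) of the given domains,
#' reorders every matrix to the shared sorted order, and records the genes
#' dropped from each domain.
#'
#' @param domains List of [expression_domain()] objects whose matrices
#'   carry gene identifiers as row names.
#' @return A [multidomain_dataset()] over the intersection; the per-domain
#'   dropped genes are attached as attribute `"dropped"`.
#' @export
align_gene_index <- function(domains) {
  if (inherits(domains, "expression_domain")) domains <- list(domains)
  if (length(domains) < 1L) stop("at least one domain is required")
  ids <- lapply(domains, function(d) rownames(d$values))
  if (any(vapply(ids, is.null, logical(1))))
    stop("every domain needs gene identifiers as row names")
  shared <- sort(Reduce(intersect, ids))
  if (length(shared) == 0L)
    stop("the domains share no gene identifiers")
  dropped <- lapply(domains, function(d)
    setdiff(rownames(d$values), shared))
  names(dropped) <- vapply(domains, `[[`, character(1), "domain_id")
  doms <- lapply(domains, function(d)
    expression_domain(d$values[shared, , drop = FALSE], d$domain_id,
                      cell_ids = d$cell_ids))
  out <- multidomain_dataset(doms, gene_ids = shared)
  attr(out, "dropped") <- dropped
  out
}

#' Write a fitted model to an output directory
#'
#' Emits per-domain assignment TSVs (`cell_id`, `cluster`), a ranked marker
#' TSV (`gene_id`, `coefficient`, `rank`, exactly lambda rows), per-domain
#' center TSVs, the objective trace, and a JSON run report (parameters,
#' seed, convergence, package version).
#'
#' @param result A [scvdmc()] fit.
#' @param dataset The dataset it was fitted on.
#' @param outdir Output directory (created if missing).
#' @return A named list (the manifest) of the files written.
#' @export
write_results <- function(result, dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (d in seq_along(dataset$domains)) {
    id <- names(dataset$domains)[d]
    af <- file.path(outdir, paste0("assignments_", id, ".tsv"))
    utils::write.table(
      data.frame(cell_id = dataset$domains[[d]]$cell_ids,
                 cluster = result$labels[[d]]),
      af, sep = "\t", quote = FALSE, row.names = FALSE)
    cf <- file.path(outdir, paste0("centers_", id, ".tsv"))
    cdf <- data.frame(gene_id = dataset$gene_ids,
                      signif17(result$U[[d]]), check.names = FALSE)
    colnames(cdf) <- c("gene_id",
                       paste0("cluster_", seq_len(ncol(result$U[[d]]))))
    utils::write.table(cdf, cf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest[[paste0("assignments_", id)]] <- af
    manifest[[paste0("centers_", id)]] <- cf
  }
  mk <- result$markers[order(result$coefficients[result$markers])]
  mf <- file.path(outdir, "markers.tsv")
  utils::write.table(
    data.frame(gene_id = mk,
               coefficient = unname(result$coefficients[mk]),
               rank = seq_along(mk)),
    mf, sep = "\t", quote = FALSE, row.names = FALSE)
  tf <- file.path(outdir, "objective_trace.tsv")
  utils::write.table(
    data.frame(iteration = seq_along(result$objective_trace),
               objective = result$objective_trace),
    tf, sep = "\t", quote = FALSE, row.names = FALSE)
  rf <- file.path(outdir, "run_report.json")
  jsonlite::write_json(
    list(params = unclass(result$params),
         n_iter = result$n_iter,
         converged = result$converged,
         final_objective = utils::tail(result$objective_trace, 1),
         n_genes = n_genes(dataset),
         n_cells = as.list(n_cells(dataset)),
         package_version =
           as.character(utils::packageVersion("scVDMC"))),
    rf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$markers <- mf
  manifest$objective_trace <- tf
  manifest$run_report <- rf
  manifest
}
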