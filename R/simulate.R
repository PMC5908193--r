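#' Configuration for the multi-domain simulator
#'
#' Describes a synthetic multi-population single-cell experiment: cells from
#' `k_true` ground-truth cell types that are separated only in a small
#' `n_markers`-dimensional marker-gene subspace, surrounded by hundreds of
#' uninformative genes, and corrupted per domain by an orthogonal rotation
#' over the first `mixing_dims` gene coordinates (mixing the markers with a
#' non-marker gene), per-gene rescaling, and additive noise. The defaults
#' reproduce the canonical demonstration scenario: 100 cells in three
#' populations (n = 33, 33, 34), 1000 genes, two planted marker genes, four
#' cell types.
#'
#' @param D Number of domains (populations).
#' @param cells_per_domain Integer vector of length `D`.
#' @param k_true Number of ground-truth cell types.
#' @param m_total Total number of genes.
#' @param n_markers Number of planted marker genes (placed at gene indices
#'   `1..n_markers`).
#' @param cluster_spread Within-cluster standard deviation in marker space;
#'   also the standard deviation of the uninformative genes.
#' @param center_scale Scale (standard deviation) of the true cluster-center
#'   coordinates; centers are redrawn until mutually separated by at least
#'   `center_scale`.
#' @param noise_sd Standard deviation of the additive noise applied to all
#'   genes after rotation and rescaling.
#' @param rotate Apply the per-domain orthogonal rotation?
#' @param rescale_range Length-2 positive range from which per-gene,
#'   per-domain scale factors are drawn uniformly.
#' @param mixing_dims Size of the leading gene block the rotation acts on
#'   (at least `n_markers`; default `n_markers + 1`, mixing one non-marker
#'   gene into the marker subspace).
#' @param rotation `"bounded"` (default): a composition of random Givens
#'   rotations with angles uniform in `[-max_angle, max_angle]`, which
#'   misaligns the domains while the planted markers remain the dominant
#'   signal carriers; `"haar"`: a uniform (Haar) random orthogonal matrix
#'   via QR of a standard Gaussian matrix with sign correction, under which
#'   the mixed genes become statistically exchangeable.
#' @param max_angle Maximum Givens angle (radians) for bounded rotations.
#' @param proportions Optional cell-type proportions (length `k_true`);
#'   equal by default.
#' @param seed Integer seed; the whole draw is deterministic given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(D = 3L,
                              cells_per_domain = c(33L, 33L, 34L),
                              k_true = 4L,
                              m_total = 1000L,
                              n_markers = 2L,
                              cluster_spread = 0.4,
                              center_scale = 4,
                              noise_sd = 0.2,
                              rotate = TRUE,
                              rescale_range = c(0.9, 1.1),
                              mixing_dims = n_markers + 1L,
                              rotation = c("bounded", "haar"),
                              max_angle = pi / 12,
                              proportions = NULL,
                              seed = 1L) {
  rotation <- match.arg(rotation)
  D <- as.integer(D)
  cells_per_domain <- as.integer(cells_per_domain)
  if (length(cells_per_domain) != D)
    stop("cells_per_domain must have length D = ", D)
  if (any(cells_per_domain < 1L)) stop("each domain needs at least one cell")
  if (k_true < 2L) stop("'k_true' must be at least 2")
  if (n_markers < 1L) stop("'n_markers' must be at least 1")
  if (n_markers >= m_total) stop("'n_markers' must be smaller than 'm_total'")
  if (mixing_dims < n_markers || mixing_dims > m_total)
    stop("'mixing_dims' must be in [n_markers, m_total]")
  if (cluster_spread <= 0) stop("'cluster_spread' must be positive")
  if (center_scale <= 0) stop("'center_scale' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (length(rescale_range) != 2L || any(rescale_range <= 0) ||
      rescale_range[2] < rescale_range[1])
    stop("'rescale_range' must be an increasing pair of positive reals")
  if (!is.null(proportions)) {
    if (length(proportions) != k_true || any(proportions <= 0))
      stop("'proportions' must be ", k_true, " positive values")
    proportions <- proportions / sum(proportions)
  }
  structure(list(D = D, cells_per_domain = cells_per_domain,
                 k_true = as.integer(k_true), m_total = as.integer(m_total),
                 n_markers = as.integer(n_markers),
                 cluster_spread = cluster_spread,
                 center_scale = center_scale, noise_sd = noise_sd,
                 rotate = isTRUE(rotate), rescale_range = rescale_range,
                 mixing_dims = as.integer(mixing_dims), rotation = rotation,
                 max_angle = max_angle, proportions = proportions,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# internal: Haar-uniform orthogonal matrix via QR with sign correction
haar_orthogonal <- function(p) {
  qr_ <- qr(matrix(stats::rnorm(p * p), p, p))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), p)
}

# internal: bounded-angle rotation = product of random Givens rotations over
# all coordinate pairs, angle ~ U(-max_angle, max_angle)
bounded_rotation <- function(p, max_angle) {
  R <- diag(p)
  if (p < 2L) return(R)
  pairs <- utils::combn(p, 2L)
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    th <- stats::runif(1L, -max_angle, max_angle)
    G <- diag(p)
    G[i, i] <- cos(th); G[j, j] <- cos(th)
    G[i, j] <- -sin(th); G[j, i] <- sin(th)
    R <- G %*% R
  }
  R
}

# internal: draw ground-truth centers (markers x k) that are mutually
# separated and spread along EVERY marker coordinate, so each planted
# marker individually separates cell types
draw_true_centers <- function(n_markers, k, scale) {
  repeat {
    C <- matrix(stats::rnorm(n_markers * k, sd = scale), n_markers, k)
    if (k == 1L) return(C)
    dmin <- min(stats::dist(t(C)))
    spread <- apply(C, 1L, stats::sd)
    balanced <- min(spread) / max(spread) >= 0.7
    if (dmin >= scale && all(spread >= scale / 2) && balanced) return(C)
  }
}

#' Simulate a multi-domain single-cell dataset with planted markers
#'
#' Draws `k_true` ground-truth cluster centers in the marker subspace, then
#' per domain: assigns cell labels (balanced by default), samples marker
#' coordinates as center plus isotropic Gaussian noise, fills the remaining
#' genes with label-independent Gaussian noise, applies a random orthogonal
#' rotation over the leading `mixing_dims` gene coordinates and per-gene
#' uniform rescaling, and adds global Gaussian noise. Finally all values are
#' shifted by a common constant so the dataset is non-negative (the shift
#' preserves cluster geometry).
#'
#' @param config A [simulation_config()].
#' @return A list with `dataset` (a [multidomain_dataset()]) and `truth`
#'   (class `simulation_truth`): per-domain true `labels`, the planted
#'   `marker_indices`, per-domain `transforms` (rotation matrix and scale
#'   factors), the true centers, and the global non-negativity `shift`.
#' @export
simulate_multidomain <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    centers <- draw_true_centers(cfg$n_markers, cfg$k_true, cfg$center_scale)
    gene_ids <- sprintf("gene_%04d", seq_len(cfg$m_total))
    labels <- transforms <- vector("list", cfg$D)
    domains <- vector("list", cfg$D)
    for (d in seq_len(cfg$D)) {
      n <- cfg$cells_per_domain[d]
      prop <- cfg$proportions
      if (is.null(prop)) prop <- rep(1 / cfg$k_true, cfg$k_true)
      base <- rep(seq_len(cfg$k_true), times = floor(prop * n))
      if (length(base) < n)
        base <- c(base, sample(seq_len(cfg$k_true), n - length(base),
                               replace = TRUE, prob = prop))
      lab <- sample(base, n)
      X <- matrix(stats::rnorm(cfg$m_total * n, sd = cfg$cluster_spread),
                  cfg$m_total, n)
      X[seq_len(cfg$n_markers), ] <-
        centers[, lab, drop = FALSE] + X[seq_len(cfg$n_markers), , drop = FALSE]
      if (cfg$rotate && cfg$mixing_dims >= 2L) {
        R <- switch(cfg$rotation,
                    bounded = bounded_rotation(cfg$mixing_dims, cfg$max_angle),
                    haar = haar_orthogonal(cfg$mixing_dims))
        idx <- seq_len(cfg$mixing_dims)
        X[idx, ] <- R %*% X[idx, , drop = FALSE]
      } else {
        R <- diag(cfg$mixing_dims)
      }
      scales <- stats::runif(cfg$m_total, cfg$rescale_range[1],
                             cfg$rescale_range[2])
      X <- X * scales
      if (cfg$noise_sd > 0)
        X <- X + matrix(stats::rnorm(cfg$m_total * n, sd = cfg$noise_sd),
                        cfg$m_total, n)
      rownames(X) <- gene_ids
      labels[[d]] <- lab
      transforms[[d]] <- list(rotation = R, scales = scales)
      domains[[d]] <- X
    }
    shift <- max(0, -min(vapply(domains, min, numeric(1))))
    doms <- lapply(seq_len(cfg$D), function(d) {
      expression_domain(domains[[d]] + shift,
                        domain_id = paste0("domain_", d),
                        cell_ids = sprintf("d%d_cell_%03d", d,
                                           seq_len(ncol(domains[[d]]))))
    })
    names(labels) <- names(transforms) <- paste0("domain_", seq_len(cfg$D))
    list(dataset = multidomain_dataset(doms, gene_ids = gene_ids),
         truth = structure(
           list(labels = labels,
                marker_indices = seq_len(cfg$n_markers),
                marker_ids = gene_ids[seq_len(cfg$n_markers)],
                transforms = transforms,
                centers = centers,
                shift = shift,
                config = cfg),
           class = "simulation_truth"))
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Emits each domain as either a dense TSV or a MatrixMarket triplet with
#' gene/barcode sidecars (see [write_domain()]), plus `truth.tsv`
#' (`cell_id`, `domain`, `true_label`) and `markers.txt` (one planted marker
#' gene identifier per line).
#'
#' @param sim Result of [simulate_multidomain()].
#' @param outdir Output directory (created if missing).
#' @param format `"dense-tsv"` or `"matrixmarket"`.
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, outdir, format = c("dense-tsv",
                                                     "matrixmarket")) {
  format <- match.arg(format)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (d in seq_along(sim$dataset$domains)) {
    dom <- sim$dataset$domains[[d]]
    base <- file.path(outdir, dom$domain_id)
    files <- c(files, write_domain(dom, base, format = format))
  }
  truth <- do.call(rbind, lapply(names(sim$truth$labels), function(id) {
    data.frame(cell_id = sim$dataset$domains[[id]]$cell_ids,
               domain = id,
               true_label = sim$truth$labels[[id]])
  }))
  tf <- file.path(outdir, "truth.tsv")
  utils::write.table(truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  mf <- file.path(outdir, "markers.txt")
  writeLines(sim$truth$marker_ids, mf)
  invisible(c(files, tf, mf))
}
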