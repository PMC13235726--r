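#' Run one preprocessing pipeline configuration
#'
#' Executes the full preprocessing chain for a single grid point:
#' normalization, feature selection, per-gene z-score scaling (values
#' clipped at +10), PCA on the scaled selected features, shared-nearest-
#' neighbor graph construction on the first `n_pcs` components (k = 20
#' neighbors, Jaccard-weighted edges, edges below 1/15 pruned), Louvain
#' modularity clustering at the configured resolution, and a seeded 2-D
#' UMAP embedding (30 neighbors, min_dist 0.3). Every stochastic stage
#' draws from its own sub-seed derived from `seed` and the `config_id`, so
#' identical inputs and seed give identical results regardless of the order
#' in which configurations are executed.
#'
#' @param counts A [count_matrix()]; must have more cells than
#'   `config$n_pcs`.
#' @param config A [pipeline_config()].
#' @param seed Integer seed for the run.
#' @return A `pipeline_result`: list with `config`, `pc_scores`
#'   (cells x n_pcs), `embedding_umap` and `embedding_pca` (cells x 2),
#'   `cluster_labels` (contiguous integers from 0, ordered by decreasing
#'   cluster size), `n_clusters`, and `seed`.
#' @export
run_pipeline <- function(counts, config, seed = 1L) {
  stopifnot(is_count_matrix(counts), inherits(config, "pipeline_config"))
  n_cells <- ncol(counts$counts)
  norm <- normalize_counts(counts, config$normalization)
  feats <- select_features(norm, counts, config$feature_mode)
  if (config$n_pcs >= min(n_cells, length(feats))) {
    stopf("n_pcs = %d must be smaller than both the number of cells (%d) and selected features (%d)",
          config$n_pcs, n_cells, length(feats))
  }
  scaled <- scale_genes(norm[feats, , drop = FALSE])

  pc <- pca_scores(t(scaled), config$n_pcs)
  rownames(pc) <- counts$cell_ids

  cl_seed <- derive_seed(seed, "cluster", config$config_id)
  labels <- with_seed(cl_seed, snn_louvain(pc, resolution = config$resolution))

  um_seed <- derive_seed(seed, "umap", config$config_id)
  nb <- min(30L, n_cells - 1L)
  um <- with_seed(um_seed,
    uwot::umap(pc, n_neighbors = nb, min_dist = 0.3,
               n_threads = 1, n_sgd_threads = 0))
  dimnames(um) <- list(counts$cell_ids, c("UMAP1", "UMAP2"))

  structure(
    list(
      config = config,
      pc_scores = pc,
      embedding_umap = um,
      embedding_pca = pc[, 1:2, drop = FALSE],
      cluster_labels = labels,
      n_clusters = length(unique(labels)),
      seed = as.integer(seed)
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result %s: %d cells, %d PCs, %d clusters\n",
              x$config$config_id, nrow(x$pc_scores), ncol(x$pc_scores),
              x$n_clusters))
  invisible(x)
}

# Per-gene z-score with upper clip at +10; constant genes map to 0.
scale_genes <- function(m, clip_max = 10) {
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  sdv[sdv == 0] <- Inf
  z <- (m - mu) / sdv
  z[z > clip_max] <- clip_max
  z
}

# Exact PCA with a deterministic sign convention (largest-magnitude loading
# of each component is positive).
pca_scores <- function(x, n_pcs) {
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  sweep(p$x, 2L, flip, `*`)
}

# Shared-nearest-neighbor graph (k neighbors incl. self, Jaccard weights,
# prune < 1/15) + Louvain modularity communities at the given resolution.
# Returns 0-based contiguous labels ordered by decreasing cluster size.
snn_louvain <- function(pc, resolution, k = 20L, prune = 1 / 15) {
  n <- nrow(pc)
  k <- min(k, n)
  nn <- RANN::nn2(pc, k = k)$nn.idx
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k), j = as.vector(nn), x = 1, dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(adj)
  snn <- methods::as(shared, "TsparseMatrix")
  jac <- snn@x / (2 * k - snn@x)
  keep <- jac >= prune & snn@i < snn@j
  g <- igraph::graph_from_data_frame(
    data.frame(from = snn@i[keep] + 1L, to = snn@j[keep] + 1L,
               weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  memb <- igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  relabel_by_size(as.integer(memb))
}

# Map arbitrary integer labels to 0-based contiguous labels, largest
# cluster first; ties broken by first occurrence.
relabel_by_size <- function(labels) {
  tab <- table(labels)
  ord <- names(tab)[order(-as.integer(tab), match(names(tab), unique(as.character(labels))))]
  as.integer(match(as.character(labels), ord)) - 1L
}
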