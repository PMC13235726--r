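#' Depth scaling factor between a spatial reference and an scRNA-seq dataset
#'
#' The ratio of the mean per-cell library size of the spatial (e.g. imaging-
#' based in-situ) dataset to that of the scRNA-seq dataset. Values below 1
#' mean the spatial platform is shallower; a value above 1 triggers
#' per-cell clamping downstream (reads cannot be invented by subsampling).
#'
#' @param sc scRNA-seq [count_matrix()].
#' @param xen Spatial reference [count_matrix()].
#' @return A positive scalar.
#' @export
scaling_factor <- function(sc, xen) {
  stopifnot(is_count_matrix(sc), is_count_matrix(xen))
  if (ncol(sc$counts) == 0L || ncol(xen$counts) == 0L) stopf("empty count matrix")
  mean_sc <- mean(library_sizes(sc))
  mean_xen <- mean(library_sizes(xen))
  if (mean_sc == 0 || mean_xen == 0) stopf("zero mean library size")
  mean_xen / mean_sc
}

#' Downsample one cell's counts to a target library size
#'
#' Draws `target` reads without replacement from the multiset of the cell's
#' reads, i.e. a multivariate hypergeometric sample: the output sums to
#' `target` exactly and no entry exceeds its input entry. Sampling is
#' sequential-conditional (one `rhyper` draw per nonzero gene).
#'
#' @param cell_counts Non-negative integer vector.
#' @param target Non-negative integer, at most `sum(cell_counts)`.
#' @param seed Optional seed; if `NULL`, draws from the current RNG stream.
#' @param replace If `TRUE`, sample with replacement instead (multinomial on
#'   read proportions), for sensitivity analysis; the without-replacement
#'   scheme is the default and the faithful model of read subsampling.
#' @return Integer vector of the same length as `cell_counts`.
#' @examples
#' downsample_cell(c(4, 0, 6), 5, seed = 1)
#' @export
downsample_cell <- function(cell_counts, target, seed = NULL, replace = FALSE) {
  if (any(cell_counts < 0) || any(cell_counts != round(cell_counts))) {
    stopf("cell_counts must be non-negative integers")
  }
  if (target < 0 || target != round(target)) stopf("target must be a non-negative integer")
  total <- sum(cell_counts)
  if (target > total) {
    stopf("target (%d) exceeds the cell's library size (%d)", target, total)
  }
  run <- function() {
    if (replace) {
      if (target == 0) return(integer(length(cell_counts)))
      return(as.integer(stats::rmultinom(1, target, cell_counts / total)))
    }
    out <- integer(length(cell_counts))
    rem <- total
    left <- as.integer(target)
    for (g in which(cell_counts > 0)) {
      if (left == 0L) break
      rem <- rem - cell_counts[g]
      if (rem == 0L) { out[g] <- left; left <- 0L; break }
      x <- stats::rhyper(1, cell_counts[g], rem, left)
      out[g] <- x
      left <- left - x
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a shallow reduced-panel spatial dataset from annotated scRNA-seq
#'
#' Emulates an imaging-based spatial dataset from an annotated scRNA-seq
#' sample by (1) restricting both datasets to their shared genes,
#' (2) computing the depth [scaling_factor()] on the restricted matrices,
#' (3) setting each scRNA-seq cell's target library size to
#' `round(library_size * factor)` (round-half-to-even; clamped to the
#' cell's own library size, with a warning, when the factor exceeds 1), and
#' (4) downsampling each cell's reads without replacement to its target.
#' Cell-type labels are inherited unchanged.
#'
#' @param sc Annotated scRNA-seq [count_matrix()] (labels optional but
#'   typically present).
#' @param xen Spatial reference [count_matrix()] supplying the gene panel
#'   and target depth.
#' @param seed Integer seed.
#' @param replace Passed to [downsample_cell()].
#' @return A list: `counts` (the simulated [count_matrix()], genes = shared
#'   panel, cells and labels of `sc`) and `spec` (a `simulation_spec` with
#'   `scaling_factor`, `shared_gene_ids`, `per_cell_targets`, `seed`).
#' @export
simulate_xenium <- function(sc, xen, seed = 1L, replace = FALSE) {
  stopifnot(is_count_matrix(sc), is_count_matrix(xen))
  shared <- intersect(sc$gene_ids, xen$gene_ids)
  if (length(shared) == 0L) stopf("no shared genes between the two datasets")
  sc_r <- subset_counts(sc, genes = match(shared, sc$gene_ids))
  xen_r <- subset_counts(xen, genes = match(shared, xen$gene_ids))
  fac <- scaling_factor(sc_r, xen_r)
  libs <- library_sizes(sc_r)
  targets <- round(libs * fac)
  if (fac > 1 && any(targets > libs)) {
    warning(sprintf("scaling factor %.3g > 1: targets clamped to each cell's library size", fac))
  }
  targets <- pmin(pmax(targets, 0), libs)
  m <- as.matrix(sc_r$counts)
  sim <- with_seed(seed, {
    vapply(seq_len(ncol(m)), function(c) {
      as.integer(downsample_cell(m[, c], targets[c], replace = replace))
    }, integer(nrow(m)))
  })
  sim <- matrix(sim, nrow = nrow(m), dimnames = dimnames(m))
  list(
    counts = count_matrix(sim, shared, sc_r$cell_ids, sc_r$labels),
    spec = structure(
      list(scaling_factor = fac, shared_gene_ids = shared,
           per_cell_targets = as.integer(targets), seed = as.integer(seed)),
      class = "simulation_spec"
    )
  )
}

#' Filter cells by library size and detected-gene thresholds
#'
#' Three preset stringencies, applied before preprocessing: cells are kept
#' when their library size and number of detected genes both meet the
#' threshold, and genes detected in zero remaining cells are dropped.
#' The presets (library size >= 50/150/300, detected genes >= 10/25/50 for
#' lenient/medium/strict) are nested by construction, so strict-pass cells
#' are a subset of medium-pass cells, which are a subset of lenient-pass
#' cells.
#'
#' @param counts A [count_matrix()].
#' @param stringency `"lenient"`, `"medium"` or `"strict"`.
#' @return The filtered [count_matrix()] with attributes `n_cells_removed`
#'   and `n_genes_removed`.
#' @export
apply_cell_filter <- function(counts, stringency = c("lenient", "medium", "strict")) {
  stringency <- match.arg(stringency)
  stopifnot(is_count_matrix(counts))
  th <- switch(stringency,
    lenient = c(lib = 50, genes = 10),
    medium = c(lib = 150, genes = 25),
    strict = c(lib = 300, genes = 50)
  )
  libs <- library_sizes(counts)
  ngenes <- Matrix::colSums(counts$counts > 0)
  keep_cells <- which(libs >= th["lib"] & ngenes >= th["genes"])
  if (length(keep_cells) == 0L) {
    stopf("'%s' filter removed all %d cells", stringency, ncol(counts$counts))
  }
  out <- subset_counts(counts, cells = keep_cells)
  keep_genes <- which(Matrix::rowSums(out$counts > 0) > 0)
  n_genes_removed <- nrow(out$counts) - length(keep_genes)
  out <- subset_counts(out, genes = keep_genes)
  attr(out, "n_cells_removed") <- ncol(counts$counts) - length(keep_cells)
  attr(out, "n_genes_removed") <- n_genes_removed
  out
}

#' Generate a synthetic annotated scRNA-seq dataset with a spatial reference
#'
#' A clustered negative-binomial generator standing in for real annotated
#' tissue pairs, so the whole selection and benchmarking machinery runs
#' offline. Gene base expression levels are drawn from a heavy-tailed
#' log-normal; each cell type up-regulates its own disjoint block of
#' `de_fraction` of the genes by `fold_change`; per-cell library sizes are
#' log-normal around `libsize_mean`; counts are negative-binomial
#' (dispersion `size = 2`) around `libsize * expression share`. The
#' companion spatial reference is generated from the same type profiles on
#' a random 20% gene panel at 10% of the depth, mimicking a reduced-panel
#' in-situ platform.
#'
#' @param n_cells Number of scRNA-seq cells (split evenly across types).
#' @param n_genes Number of genes.
#' @param n_types Number of cell types (>= 1).
#' @param de_fraction Fraction of genes up-regulated per type, in `(0, 1]`;
#'   `n_types * de_fraction` must not exceed 1.
#' @param fold_change Up-regulation factor, strictly > 1.
#' @param libsize_mean Mean per-cell library size of the scRNA-seq data.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A list: `sc` (labeled [count_matrix()]) and `xen`
#'   (the reduced-panel shallow reference, unlabeled).
#' @export
generate_synthetic_scenario <- function(n_cells = 600L, n_genes = 2000L,
                                        n_types = 3L, de_fraction = 0.05,
                                        fold_change = 8, libsize_mean = 2000,
                                        seed = 1L) {
  if (n_types < 1L) stopf("n_types must be >= 1")
  if (de_fraction <= 0 || de_fraction > 1) stopf("de_fraction must lie in (0, 1]")
  if (fold_change <= 1) stopf("fold_change must be strictly greater than 1")
  n_de <- floor(de_fraction * n_genes)
  if (n_types * n_de > n_genes) stopf("n_types * de_fraction exceeds the gene panel")
  if (n_de == 0L && n_types > 1L) stopf("de_fraction too small: no marker genes per type")
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.3)
    de_pool <- sample.int(n_genes, n_types * n_de)
    profiles <- matrix(base, n_genes, n_types)
    for (k in seq_len(n_types)) {
      idx <- de_pool[seq.int((k - 1L) * n_de + 1L, k * n_de)]
      profiles[idx, k] <- profiles[idx, k] * fold_change
    }
    profiles <- sweep(profiles, 2L, colSums(profiles), `/`)

    types <- rep(seq_len(n_types), length.out = n_cells)
    labels <- paste0("type", types)
    sc <- nb_counts(profiles[, types, drop = FALSE], libsize_mean, n_genes,
                    prefix = "sc")
    sc_cm <- count_matrix(sc, paste0("gene", seq_len(n_genes)),
                          paste0("sc_cell", seq_len(n_cells)), labels)

    panel <- sort(sample.int(n_genes, max(1L, round(0.2 * n_genes))))
    xen_profiles <- profiles[panel, types, drop = FALSE]
    xen_profiles <- sweep(xen_profiles, 2L, colSums(xen_profiles), `/`)
    xen <- nb_counts(xen_profiles, 0.1 * libsize_mean, length(panel),
                     prefix = "xen")
    xen_cm <- count_matrix(xen, paste0("gene", panel),
                           paste0("xen_cell", seq_len(n_cells)), NULL)
    list(sc = sc_cm, xen = xen_cm)
  })
}

# NB counts around libsize * per-type expression shares (columns = cells)
nb_counts <- function(cell_profiles, libsize_mean, n_genes, prefix, sdlog = 0.3) {
  n_cells <- ncol(cell_profiles)
  libs <- stats::rlnorm(n_cells, meanlog = log(libsize_mean) - sdlog^2 / 2,
                        sdlog = sdlog)
  mu <- sweep(cell_profiles, 2L, libs, `*`)
  matrix(stats::rnbinom(length(mu), mu = mu, size = 2), n_genes, n_cells)
}
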