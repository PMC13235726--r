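#' Construct a validated gene-by-cell count matrix
#'
#' The basic data container of the package: a non-negative integer matrix
#' with genes in rows and cells in columns, unique identifiers on both
#' margins, and optional per-cell ground-truth type labels (used by the
#' benchmark machinery, never by the selection procedure itself).
#'
#' @param counts A genes x cells matrix of non-negative integers; dense
#'   `matrix` or any `Matrix` sparse class.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   `rownames(counts)`).
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   `colnames(counts)`).
#' @param labels Optional character vector of per-cell type labels.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `gene_ids`, `cell_ids` and `labels`.
#' @examples
#' m <- matrix(rpois(12, 2), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' cm <- count_matrix(m)
#' dim(cm)
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         cell_ids = colnames(counts), labels = NULL) {
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stopf("counts must carry gene and cell identifiers (dimnames or explicit arguments)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts)) {
    stopf("identifier lengths (%d genes, %d cells) do not match matrix dimensions %d x %d",
          length(gene_ids), length(cell_ids), nrow(counts), ncol(counts))
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stopf("duplicate gene identifiers: %s", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) {
    dup <- unique(cell_ids[duplicated(cell_ids)])
    stopf("duplicate cell identifiers: %s", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  vals <- counts@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals)))) {
    bad <- which(vals < 0 | vals != round(vals))[1L]
    stopf("counts must be non-negative integers; offending value %g", vals[bad])
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(cell_ids)) {
      stopf("labels length (%d) does not match number of cells (%d)",
            length(labels), length(cell_ids))
    }
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids, labels = labels),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$labels)) "" else
                sprintf(" (%d label classes)", length(unique(x$labels)))))
  invisible(x)
}

# Per-cell library sizes (column sums).
library_sizes <- function(x) {
  stopifnot(is_count_matrix(x))
  Matrix::colSums(x$counts)
}

# Subset a count_matrix by gene and/or cell index, keeping labels aligned.
subset_counts <- function(x, genes = NULL, cells = NULL) {
  stopifnot(is_count_matrix(x))
  m <- x$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  labels <- x$labels
  if (!is.null(labels) && !is.null(cells)) labels <- labels[cells]
  count_matrix(m, rownames(m), colnames(m), labels)
}
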