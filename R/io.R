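#' Read a count matrix from disk
#'
#' Two plain-text layouts are supported:
#'
#' * `mtx_dir` — a 10x-style directory with `matrix.mtx` (Matrix Market
#'   triplet, 1-based indices), `features.tsv` (gene ids in column 1),
#'   `barcodes.tsv` (cell ids), and optionally `labels.tsv`
#'   (cell_id TAB label). Orientation is auto-detected from the features
#'   file: if the matrix rows match the number of features it is taken as
#'   genes x cells, otherwise it is transposed.
#' * `dense_tsv` — a dense tab-separated table, genes in rows (first column
#'   gene ids, header row of cell ids).
#'
#' Cells with zero library size are rejected here: downstream normalization
#' divides by library size, and silently dropping cells would desynchronize
#' labels.
#'
#' @param path Directory (`mtx_dir`) or file (`dense_tsv`).
#' @param format `"mtx_dir"` or `"dense_tsv"`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("mtx_dir", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stopf("directory not found: %s", path)
    need <- file.path(path, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
    missing <- need[!file.exists(need)]
    if (length(missing)) stopf("missing file(s): %s", paste(missing, collapse = ", "))
    m <- Matrix::readMM(need[1])
    feats <- utils::read.table(need[2], sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(need[3], sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (nrow(m) == length(feats) && ncol(m) == length(cells)) {
      # genes x cells as stored
    } else if (ncol(m) == length(feats) && nrow(m) == length(cells)) {
      m <- Matrix::t(m)
    } else {
      stopf("matrix dimensions %d x %d match neither %d features x %d barcodes nor its transpose",
            nrow(m), ncol(m), length(feats), length(cells))
    }
    check_integer_entries(m)
    labels <- NULL
    labfile <- file.path(path, "labels.tsv")
    if (file.exists(labfile)) {
      lab <- utils::read.table(labfile, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
      labels <- lab[[2]][match(cells, lab[[1]])]
    }
    cm <- count_matrix(m, feats, cells, labels)
  } else {
    if (!file.exists(path)) stopf("file not found: %s", path)
    tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                             check.names = FALSE)
    m <- as.matrix(tab)
    check_integer_entries(m)
    cm <- count_matrix(m, rownames(tab), colnames(tab), NULL)
  }
  libs <- library_sizes(cm)
  if (any(libs == 0)) {
    stopf("cells with zero library size: %s (filter before loading)",
          paste(utils::head(cm$cell_ids[libs == 0], 10), collapse = ", "))
  }
  cm
}

check_integer_entries <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    t <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
    bad <- which(t@x < 0 | t@x != round(t@x))
    if (length(bad)) {
      stopf("invalid count %g at (%d, %d): entries must be non-negative integers",
            t@x[bad[1]], t@i[bad[1]] + 1L, t@j[bad[1]] + 1L)
    }
  } else {
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad)) {
      stopf("invalid count %g at (%d, %d): entries must be non-negative integers",
            m[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2])
    }
  }
}

#' Write a count matrix as a 10x-style Matrix Market directory
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and, when labels are
#' present, `labels.tsv`; the exact inverse of [read_counts()].
#'
#' @param x A [count_matrix()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(is_count_matrix(x))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(path, "features.tsv"))
  writeLines(x$cell_ids, file.path(path, "barcodes.tsv"))
  if (!is.null(x$labels)) {
    utils::write.table(data.frame(x$cell_ids, x$labels),
                       file.path(path, "labels.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Serialize a run manifest to JSON and back (lossless for the fields used).
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
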