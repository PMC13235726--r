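#' Select the best preprocessing pipeline by visual tournament
#'
#' The one-call entry point. Every configuration of `grid` is executed on
#' the counts ([run_pipeline()]), the chosen-basis embedding of each result
#' is rendered as a standardized image ([render_embedding()]), and a
#' sequential pairwise tournament ([run_tournament()]) driven by `backend`
#' selects the winner, whose full preprocessing result is returned for
#' downstream analysis.
#'
#' All randomness flows from `seed` through per-configuration,
#' per-stage sub-seeds, so a run with a deterministic backend is exactly
#' reproducible and independent of execution order.
#'
#' @param counts A [count_matrix()] that has already undergone cell
#'   filtering (see [apply_cell_filter()]).
#' @param grid A [pipeline_grid()]; all 72 default configurations unless
#'   subset.
#' @param basis `"umap"` (default) or `"pca"`: which embedding the judge
#'   sees.
#' @param backend A `judge_backend` ([llm_judge()], [oracle_judge()],
#'   [noisy_judge()]).
#' @param seed Integer master seed.
#' @param shots 1 (single query per comparison) or an odd number of queries
#'   aggregated by [majority_vote()].
#' @param outdir Optional directory; when given, per-config images
#'   (`plots/<basis>/<config_id>.png`), the winner's cluster labels and
#'   embedding (TSV), the winning configuration (JSON) and the run manifest
#'   (JSON) are persisted there.
#' @param render Set `FALSE` to skip image rendering when the backend only
#'   needs scores (oracle benchmarking); the judge then receives
#'   lightweight stubs carrying the `config_id`.
#' @return An object of class `scjudge`: list with `winner`
#'   (the winning `pipeline_result`), `tournament`, `results`, `images`,
#'   `grid`, `basis` and `manifest`.
#' @examples
#' \donttest{
#' sim <- generate_synthetic_scenario(n_cells = 150, n_genes = 400, seed = 1)
#' grid <- pipeline_grid(normalization = "lognorm", n_pcs = 5)
#' results <- lapply(grid, function(cfg) run_pipeline(sim$sc, cfg, seed = 1))
#' scores <- vapply(results, function(r)
#'   compute_metrics(r, sim$sc$labels)$ari, 0)
#' fit <- scjudge(sim$sc, grid, backend = oracle_judge(scores), seed = 1)
#' print(fit)
#' }
#' @export
scjudge <- function(counts, grid = pipeline_grid(), basis = c("umap", "pca"),
                    backend, seed = 1L, shots = 1L, outdir = NULL,
                    render = TRUE) {
  basis <- match.arg(basis)
  stopifnot(is_count_matrix(counts), inherits(backend, "judge_backend"))
  if (!inherits(grid, "pipeline_grid")) {
    if (is.list(grid) && all(vapply(grid, inherits, TRUE, "pipeline_config"))) {
      grid <- structure(grid, class = c("pipeline_grid", "list"))
    } else stopf("grid must be a pipeline_grid or list of pipeline_config")
  }
  timings <- list()

  t0 <- Sys.time()
  results <- lapply(grid, function(cfg) run_pipeline(counts, cfg, seed = seed))
  timings$preprocess_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- Sys.time()
  images <- lapply(results, function(r) {
    if (!render) {
      return(list(config_id = r$config$config_id, basis = basis))
    }
    emb <- if (basis == "umap") r$embedding_umap else r$embedding_pca
    render_embedding(emb, r$cluster_labels, basis = basis,
                     seed = derive_seed(seed, "render", r$config$config_id),
                     config_id = r$config$config_id)
  })
  timings$render_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- Sys.time()
  tour_backend <- if (shots > 1L) {
    new_judge_backend(
      sprintf("%s x%d", backend$name, shots),
      function(i1, i2) majority_vote(backend, i1, i2, shots),
      backend$deterministic
    )
  } else backend
  tournament <- run_tournament(results, images, tour_backend)
  timings$tournament_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  winner <- results[[tournament$winner_index]]
  manifest <- list(
    package_version = as.character(utils::packageVersion("scjudge")),
    n_genes = nrow(counts$counts),
    n_cells = ncol(counts$counts),
    grid = vapply(grid, `[[`, "", "config_id"),
    basis = basis,
    judge = backend$name,
    shots = as.integer(shots),
    seed = as.integer(seed),
    umap = list(n_neighbors = 30, min_dist = 0.3),
    snn = list(k = 20, prune = 1 / 15),
    scale_clip = 10,
    n_results = length(results),
    n_comparisons = length(tournament$comparisons),
    winner_config_id = tournament$winner_config_id,
    timings = timings,
    outputs = character(0)
  )

  fit <- structure(
    list(winner = winner, tournament = tournament, results = results,
         images = images, grid = grid, basis = basis, manifest = manifest),
    class = "scjudge"
  )
  if (!is.null(outdir)) fit <- persist_scjudge(fit, outdir)
  fit
}

persist_scjudge <- function(fit, outdir) {
  plotdir <- file.path(outdir, "plots", fit$basis)
  dir.create(plotdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  for (img in fit$images) {
    if (is.null(img$image_bytes)) next
    f <- file.path(plotdir, paste0(gsub("[|]", "_", img$config_id), ".png"))
    writeBin(img$image_bytes, f)
    outputs <- c(outputs, f)
  }
  w <- fit$winner
  lab_f <- file.path(outdir, "winner_clusters.tsv")
  utils::write.table(
    data.frame(cell_id = rownames(w$pc_scores), cluster = w$cluster_labels),
    lab_f, sep = "\t", quote = FALSE, row.names = FALSE)
  emb_f <- file.path(outdir, "winner_embedding.tsv")
  utils::write.table(
    data.frame(cell_id = rownames(w$embedding_umap), w$embedding_umap),
    emb_f, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_f <- file.path(outdir, "winner_config.json")
  jsonlite::write_json(unclass(w$config), cfg_f, auto_unbox = TRUE)
  trace_f <- file.path(outdir, "tournament.jsonl")
  writeLines(vapply(fit$tournament$comparisons, function(cp) {
    jsonlite::toJSON(list(challenger = cp$challenger_id,
                          incumbent = cp$incumbent_id,
                          winner = cp$decision$winner,
                          attempts = cp$decision$attempts,
                          raw_responses = cp$decision$raw_responses),
                     auto_unbox = TRUE)
  }, ""), trace_f)
  fit$manifest$outputs <- c(outputs, lab_f, emb_f, cfg_f, trace_f)
  man_f <- file.path(outdir, "manifest.json")
  write_manifest(fit$manifest, man_f)
  fit
}

#' @export
print.scjudge <- function(x, ...) {
  cat("Pipeline selection by pairwise visual tournament\n")
  cat(sprintf("  candidates : %d (basis: %s, judge: %s)\n",
              length(x$results), x$basis, x$manifest$judge))
  cat(sprintf("  comparisons: %d\n", length(x$tournament$comparisons)))
  cat(sprintf("  winner     : %s (%d clusters)\n",
              x$tournament$winner_config_id, x$winner$n_clusters))
  invisible(x)
}

#' @export
summary.scjudge <- function(object, truth_labels = NULL, ...) {
  tab <- data.frame(
    config_id = vapply(object$results, function(r) r$config$config_id, ""),
    n_clusters = vapply(object$results, `[[`, 0L, "n_clusters"),
    winner = vapply(object$results, function(r)
      r$config$config_id == object$tournament$winner_config_id, TRUE),
    stringsAsFactors = FALSE
  )
  if (!is.null(truth_labels)) {
    tab$ari <- vapply(object$results, function(r)
      compute_metrics(r, truth_labels)$ari, 0)
  }
  structure(list(table = tab, winner = object$tournament$winner_config_id,
                 n_comparisons = length(object$tournament$comparisons)),
            class = "summary.scjudge")
}

#' @export
print.summary.scjudge <- function(x, ...) {
  cat(sprintf("winner: %s after %d comparisons\n\n", x$winner, x$n_comparisons))
  print(utils::head(x$table[order(-x$table$winner), ], 10), row.names = FALSE)
  invisible(x)
}

#' @export
plot.scjudge <- function(x, basis = NULL, ...) {
  basis <- if (is.null(basis)) x$basis else match.arg(basis, c("umap", "pca"))
  emb <- if (basis == "umap") x$winner$embedding_umap else x$winner$embedding_pca
  pal <- distinct_palette()
  cl <- x$winner$cluster_labels
  cols <- pal[(cl %% length(pal)) + 1L]
  graphics::plot(emb, col = cols, pch = 16, cex = 0.5,
                 xlab = paste0(toupper(basis), " 1"),
                 ylab = paste0(toupper(basis), " 2"),
                 main = x$tournament$winner_config_id, ...)
  invisible(x)
}
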