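#' Five-metric clustering evaluation of a pipeline result
#'
#' Computes the evaluation suite for one pipeline run against ground-truth
#' cell-type labels:
#'
#' * `ari` — adjusted Rand index between cluster labels and truth
#'   (via `mclust::adjustedRandIndex`).
#' * `mi` — mutual information of the two labelings in nats, from the
#'   empirical joint distribution.
#' * `silhouette` — mean silhouette width (via `cluster::silhouette`) on
#'   Euclidean distances in the pipeline's own `n_pcs`-dimensional PC space.
#' * `chi` — Calinski-Harabasz index in the same space.
#' * `one_minus_dbi` — 1 minus the Davies-Bouldin index, so that all five
#'   metrics are higher-is-better.
#'
#' The internal metrics (silhouette, CHI, DBI) are computed by default on
#' the pipeline's own cluster labels; `use_truth_labels = TRUE` switches
#' them to the ground-truth partition for sensitivity analysis. With a
#' single cluster the internal metrics are undefined and reported as `NA`
#' (never fabricated); ARI and MI are still computed.
#'
#' @param result A [run_pipeline()] result.
#' @param truth_labels Ground-truth labels aligned to the cells.
#' @param use_truth_labels Use the truth partition for the internal metrics.
#' @return A `metric_report`: named list `ari`, `silhouette`, `chi`,
#'   `one_minus_dbi`, `mi`.
#' @export
compute_metrics <- function(result, truth_labels, use_truth_labels = FALSE) {
  stopifnot(inherits(result, "pipeline_result"))
  n <- nrow(result$pc_scores)
  if (length(truth_labels) != n) {
    stopf("truth_labels length (%d) does not match cells (%d)",
          length(truth_labels), n)
  }
  cl <- result$cluster_labels
  ari <- mclust::adjustedRandIndex(cl, truth_labels)
  mi <- mutual_information(cl, truth_labels)
  internal <- if (use_truth_labels) as.integer(factor(truth_labels)) else cl
  k <- length(unique(internal))
  if (k < 2L) {
    sil <- chi <- omdbi <- NA_real_
  } else {
    sil <- mean(cluster::silhouette(as.integer(factor(internal)),
                                    stats::dist(result$pc_scores))[, "sil_width"])
    chi <- calinski_harabasz(result$pc_scores, internal)
    omdbi <- 1 - davies_bouldin(result$pc_scores, internal)
  }
  structure(
    list(ari = ari, silhouette = sil, chi = chi, one_minus_dbi = omdbi, mi = mi),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: ARI %.3f | silhouette %.3f | CHI %.1f | 1-DBI %.3f | MI %.3f nats\n",
              x$ari, x$silhouette, x$chi, x$one_minus_dbi, x$mi))
  invisible(x)
}

#' Mutual information of two discrete labelings, in nats
#'
#' @param x,y Label vectors of equal length.
#' @return Non-negative scalar (natural-log base).
#' @export
mutual_information <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  idx <- joint > 0
  sum(joint[idx] * log(joint[idx] / outer(px, py)[idx]))
}

# Between/within dispersion ratio in PC space (Euclidean).
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  lev <- unique(labels)
  k <- length(lev)
  grand <- colMeans(x)
  B <- 0; W <- 0
  for (l in lev) {
    xi <- x[labels == l, , drop = FALSE]
    ci <- colMeans(xi)
    B <- B + nrow(xi) * sum((ci - grand)^2)
    W <- W + sum(sweep(xi, 2L, ci)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# Davies-Bouldin: mean over clusters of the worst (scatter_i + scatter_j) /
# centroid distance, scatter = mean Euclidean distance to centroid.
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  lev <- unique(labels)
  k <- length(lev)
  cents <- t(vapply(lev, function(l) colMeans(x[labels == l, , drop = FALSE]),
                    numeric(ncol(x))))
  scatter <- vapply(seq_len(k), function(i) {
    xi <- x[labels == lev[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2L, cents[i, ])^2)))
  }, 0)
  db <- vapply(seq_len(k), function(i) {
    r <- vapply(seq_len(k), function(j) {
      if (i == j) return(-Inf)
      (scatter[i] + scatter[j]) / sqrt(sum((cents[i, ] - cents[j, ])^2))
    }, 0)
    max(r)
  }, 0)
  mean(db)
}

#' Scale a scenario-by-method score matrix within scenarios
#'
#' Z-scores each row (scenario) across methods using the sample standard
#' deviation, so methods become comparable across scenarios with different
#' metric scales: each row of the result has mean 0 and sd 1.
#'
#' @param values Numeric matrix, rows = scenarios, columns = methods
#'   (>= 2 columns, no constant row).
#' @return Matrix of the same shape.
#' @export
scale_across_methods <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stopf("need at least two methods per scenario")
  sds <- apply(values, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- if (is.null(rownames(values))) which(sds == 0) else rownames(values)[sds == 0]
    stopf("constant metric values in scenario(s): %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  t(scale(t(values)))[, , drop = FALSE]
}

#' Judge accuracy on sampled pipeline pairs
#'
#' The pairwise benchmark protocol: sample `n_pairs` unordered candidate
#' pairs without repetition (either any pair, or only pairs whose
#' configurations differ in exactly one of the four grid factors), discard
#' and resample pairs whose metric values tie, present each pair to the
#' judge (lower grid index as image 1; `shots > 1` uses
#' [majority_vote()]), and report the fraction of pairs where the judge
#' picked the member with the higher metric value.
#'
#' @param results List of [run_pipeline()] results.
#' @param images Aligned image list.
#' @param metrics Data frame with a `config_id` column and one column per
#'   metric (e.g. from [benchmark_metrics()]).
#' @param backend A `judge_backend`.
#' @param n_pairs Number of pairs to sample.
#' @param pair_mode `"any"` or `"single_step"`.
#' @param metric Metric column used as ground truth.
#' @param shots Odd number of judge queries per pair.
#' @param seed Sampling seed.
#' @return Accuracy in `[0, 1]`, with the sampled pair index matrix as
#'   attribute `"pairs"`.
#' @export
pairwise_accuracy <- function(results, images, metrics, backend,
                              n_pairs = 20L, pair_mode = c("any", "single_step"),
                              metric = "ari", shots = 1L, seed = 1L) {
  pair_mode <- match.arg(pair_mode)
  n <- length(results)
  if (n < 2L) stopf("need at least two candidates")
  if (!metric %in% names(metrics)) stopf("metric '%s' not present in metrics table", metric)
  ids <- vapply(results, function(r) r$config$config_id, "")
  vals <- metrics[[metric]][match(ids, metrics$config_id)]
  if (anyNA(vals)) stopf("metric '%s' undefined for some candidates", metric)

  pairs <- utils::combn(n, 2L)
  if (pair_mode == "single_step") {
    keep <- apply(pairs, 2L, function(p) {
      a <- results[[p[1]]]$config; b <- results[[p[2]]]$config
      sum(a$normalization != b$normalization,
          a$feature_mode != b$feature_mode,
          a$n_pcs != b$n_pcs,
          a$resolution != b$resolution) == 1L
    })
    pairs <- pairs[, keep, drop = FALSE]
  }
  tied <- vals[pairs[1, ]] == vals[pairs[2, ]]
  pairs <- pairs[, !tied, drop = FALSE]
  if (ncol(pairs) < n_pairs) {
    stopf("only %d eligible non-tied pairs available (%d requested)",
          ncol(pairs), n_pairs)
  }
  sel <- with_seed(seed, sample.int(ncol(pairs), n_pairs))
  pairs <- pairs[, sel, drop = FALSE]

  correct <- vapply(seq_len(n_pairs), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    dec <- if (shots > 1L) majority_vote(backend, images[[i]], images[[j]], shots)
           else judge_compare(backend, images[[i]], images[[j]])
    picked <- if (dec$winner == 1L) vals[i] else vals[j]
    picked == max(vals[i], vals[j])
  }, NA)
  acc <- mean(correct)
  attr(acc, "pairs") <- pairs
  acc
}

#' Metric table for a set of pipeline results
#'
#' @param results List of [run_pipeline()] results.
#' @param truth_labels Ground-truth labels.
#' @param use_truth_labels Passed to [compute_metrics()].
#' @return Data frame with `config_id` and the five metric columns.
#' @export
benchmark_metrics <- function(results, truth_labels, use_truth_labels = FALSE) {
  rows <- lapply(results, function(r) {
    m <- compute_metrics(r, truth_labels, use_truth_labels)
    data.frame(config_id = r$config$config_id, ari = m$ari,
               silhouette = m$silhouette, chi = m$chi,
               one_minus_dbi = m$one_minus_dbi, mi = m$mi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank of the selected pipeline under a metric
#'
#' @param winner_config_id The selected configuration.
#' @param metrics Data frame from [benchmark_metrics()].
#' @param metric Metric column name.
#' @return Integer rank (1 = best; ties share the best rank).
#' @export
rank_of_selected <- function(winner_config_id, metrics, metric = "ari") {
  if (!metric %in% names(metrics)) stopf("metric '%s' not present", metric)
  if (!winner_config_id %in% metrics$config_id) {
    stopf("winner '%s' not present in metrics table", winner_config_id)
  }
  vals <- metrics[[metric]]
  w <- vals[metrics$config_id == winner_config_id]
  if (is.na(w)) stopf("metric '%s' undefined for winner", metric)
  as.integer(rank(-vals, ties.method = "min")[metrics$config_id == winner_config_id])
}

#' Pearson correlation of two pipeline rankings
#'
#' @param ranking_a,ranking_b Equal-length (>= 3) rank vectors aligned by
#'   candidate.
#' @return Correlation in `[-1, 1]`.
#' @export
ranking_correlation <- function(ranking_a, ranking_b) {
  if (length(ranking_a) != length(ranking_b) || length(ranking_a) < 3L) {
    stopf("rankings must have equal length >= 3")
  }
  if (stats::sd(ranking_a) == 0 || stats::sd(ranking_b) == 0) {
    stopf("constant ranking has no defined correlation")
  }
  stats::cor(ranking_a, ranking_b)
}
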