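#' Select features for downstream analysis
#'
#' `mode = "all"` keeps every gene. `mode = "hvg_formula"` ranks genes by a
#' variance-stabilized dispersion statistic computed from the raw counts and
#' keeps the top [hvg_count()] of them: per-gene mean and variance are
#' computed, a loess trend of `log10(variance)` on `log10(mean)` predicts
#' the expected variance at each gene's mean, counts are standardized by the
#' trend-expected standard deviation (clipped at `sqrt(n_cells)`), and genes
#' are ranked by the variance of these standardized values. Ties are broken
#' by gene order. Constant genes have zero standardized variance and rank
#' last.
#'
#' @param normalized Dense normalized matrix from [normalize_counts()]
#'   (carried for interface symmetry; the dispersion statistic itself is
#'   computed from raw counts, which is the convention of the
#'   variance-stabilizing selector this mirrors).
#' @param counts The original [count_matrix()].
#' @param mode `"all"` or `"hvg_formula"`.
#' @return Integer vector of gene indices; for `"hvg_formula"` ordered by
#'   decreasing standardized variance.
#' @export
select_features <- function(normalized, counts, mode = feature_modes()) {
  stopifnot(is_count_matrix(counts))
  mode <- match.arg(mode)
  I <- nrow(counts$counts)
  if (I == 0L || ncol(counts$counts) == 0L) stopf("empty count matrix")
  if (mode == "all") return(seq_len(I))
  stat <- standardized_variance(counts$counts)
  n_keep <- hvg_count(I)
  order(-stat, seq_along(stat))[seq_len(n_keep)]
}

# vst-style standardized variance of raw counts; loess trend with a
# dispersion fallback when too few genes support a smooth fit.
standardized_variance <- function(m, span = 0.3) {
  m <- as.matrix(m)
  n <- ncol(m)
  mu <- rowMeans(m)
  if (n < 2L) return(rep(0, nrow(m)))
  v <- rowSums((m - mu)^2) / (n - 1)
  stat <- numeric(nrow(m))
  ok <- mu > 0 & v > 0
  if (!any(ok)) return(stat)
  exp_var <- v
  if (sum(ok) >= 10L) {
    fit <- tryCatch(
      stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = span, degree = 2),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      pred <- 10^stats::fitted(fit)
      bad <- !is.finite(pred) | pred <= 0
      pred[bad] <- v[ok][bad]
      exp_var[ok] <- pred
    }
  }
  clip <- sqrt(n)
  for (g in which(ok)) {
    z <- (m[g, ] - mu[g]) / sqrt(exp_var[g])
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    zm <- mean(z)
    stat[g] <- sum((z - zm)^2) / (n - 1)
  }
  stat
}
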