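#' @name pipeline_grid
#' @title The candidate pipeline grid
#'
#' @description
#' Each candidate preprocessing pipeline is one point of a four-factor grid:
#' a normalization method, a feature-selection mode, a number of principal
#' components, and a graph-clustering resolution. The default grid crosses
#' six normalizations, two feature modes, two PC counts (5, 20) and three
#' resolutions (0.2, 0.5, 1), giving 72 candidates.
#'
#' Enumeration order is fixed and normalization-major (normalization varies
#' slowest, then feature mode, then PC count, then resolution): with a noisy
#' judge the tournament outcome can depend on presentation order, so a fixed
#' order keeps runs reproducible.
NULL

norm_methods <- function() c("sct_analog", "lognorm", "clr", "rc", "log", "raw")
feature_modes <- function() c("all", "hvg_formula")

#' Construct a single pipeline configuration
#'
#' @param normalization One of `"sct_analog"`, `"lognorm"`, `"clr"`, `"rc"`,
#'   `"log"`, `"raw"`.
#' @param feature_mode `"all"` (use every gene) or `"hvg_formula"` (keep the
#'   top [hvg_count()] genes by standardized variance).
#' @param n_pcs Positive integer, number of principal components.
#' @param resolution Positive real, modularity resolution for clustering.
#' @return A `pipeline_config` with a stable `config_id` formed by joining
#'   the four values with `"|"` in factor order.
#' @examples
#' pipeline_config("lognorm", "all", 5, 0.5)$config_id
#' @export
pipeline_config <- function(normalization, feature_mode, n_pcs, resolution) {
  normalization <- match.arg(normalization, norm_methods())
  feature_mode <- match.arg(feature_mode, feature_modes())
  if (!is.numeric(n_pcs) || length(n_pcs) != 1L || n_pcs < 1 || n_pcs != round(n_pcs)) {
    stopf("n_pcs must be a single positive integer, got %s", deparse(n_pcs))
  }
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    stopf("resolution must be a single positive number, got %s", deparse(resolution))
  }
  n_pcs <- as.integer(n_pcs)
  structure(
    list(
      normalization = normalization,
      feature_mode = feature_mode,
      n_pcs = n_pcs,
      resolution = resolution,
      config_id = paste(normalization, feature_mode, n_pcs,
                        sprintf("%g", resolution), sep = "|")
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:", x$config_id, "\n")
  invisible(x)
}

#' Enumerate a grid of candidate pipeline configurations
#'
#' Returns the full cross-product of the supplied factor levels in a
#' deterministic normalization-major order. Each factor may be subset by
#' passing a shorter value list; an empty subset is an error.
#'
#' @param normalization Normalization methods to include.
#' @param feature_mode Feature-selection modes to include.
#' @param n_pcs PC counts to include.
#' @param resolution Clustering resolutions to include.
#' @return A list of [pipeline_config()] objects, class `pipeline_grid`.
#' @examples
#' length(pipeline_grid())                             # 72
#' length(pipeline_grid(normalization = "lognorm"))    # 12
#' @export
pipeline_grid <- function(normalization = norm_methods(),
                          feature_mode = feature_modes(),
                          n_pcs = c(5L, 20L),
                          resolution = c(0.2, 0.5, 1)) {
  for (f in c("normalization", "feature_mode", "n_pcs", "resolution")) {
    if (length(get(f)) == 0L) stopf("empty value list for grid factor '%s'", f)
  }
  normalization <- vapply(normalization, function(v) match.arg(v, norm_methods()), "")
  feature_mode <- vapply(feature_mode, function(v) match.arg(v, feature_modes()), "")
  grid <- list()
  for (nm in normalization)
    for (fm in feature_mode)
      for (np in n_pcs)
        for (rs in resolution)
          grid[[length(grid) + 1L]] <- pipeline_config(nm, fm, np, rs)
  ids <- vapply(grid, `[[`, "", "config_id")
  if (anyDuplicated(ids)) stopf("duplicate configurations in grid")
  names(grid) <- ids
  structure(grid, class = c("pipeline_grid", "list"))
}

#' @export
print.pipeline_grid <- function(x, ...) {
  cat(sprintf("pipeline_grid of %d configurations\n", length(x)))
  invisible(x)
}

#' Highly-variable-feature count for a panel of I genes
#'
#' The number of highly variable features retained when `feature_mode` is
#' `"hvg_formula"`: \eqn{a = 2 \times 10^{\lceil \log_{10}(I/2)\rceil - 1}},
#' rounded to the nearest integer and clamped to `[1, I]`. The formula keeps
#' roughly the leading order of magnitude of the panel: 2000 genes give 200
#' features, 100 genes give 20. The clamp only matters for degenerate panels
#' (`I <= 3`), where the raw formula drops below 1.
#'
#' @param I Total number of genes (positive integer).
#' @return A positive integer in `[1, I]`.
#' @examples
#' hvg_count(2000)  # 200
#' hvg_count(100)   # 20
#' hvg_count(20)    # 2
#' @export
hvg_count <- function(I) {
  if (!is.numeric(I) || length(I) != 1L || I < 1 || I != round(I)) {
    stopf("I must be a single integer >= 1, got %s", deparse(I))
  }
  # epsilon guard: log10 of an exact power of ten must not round up
  k <- ceiling(log10(I / 2) - 1e-9)
  a <- round(2 * 10^(k - 1))
  as.integer(min(max(a, 1), I))
}
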