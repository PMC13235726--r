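# Shared fixtures and independent brute-force oracles used across tests.

make_counts <- function(m, labels = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  count_matrix(m, labels = labels)
}

random_counts <- function(n_genes, n_cells, lambda = 3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
    make_counts(m)
  })
}

# Two well-separated NB clusters: disjoint marker blocks, strong fold change.
two_cluster_counts <- function(n_cells = 200, n_genes = 300, seed = 5) {
  withr::with_seed(seed, {
    half <- n_cells / 2
    base <- rep(1, n_genes)
    p1 <- base; p1[1:30] <- 40
    p2 <- base; p2[31:60] <- 40
    mu <- cbind(matrix(p1, n_genes, half), matrix(p2, n_genes, half)) * 5
    m <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = 5), n_genes, n_cells)
    make_counts(m, labels = rep(c("A", "B"), each = half))
  })
}

# Lightweight candidates for judge/tournament tests: a pipeline_result shell
# and an image stub that only carries the config_id oracle backends need.
subset_cells_fixture <- function(cm, cells) {
  m <- as.matrix(cm$counts)[, cells, drop = FALSE]
  count_matrix(m, cm$gene_ids, colnames(m),
               if (is.null(cm$labels)) NULL else cm$labels[cells])
}

stub_result <- function(config) {
  structure(list(config = config, n_clusters = 1L), class = "pipeline_result")
}

stub_candidates <- function(configs) {
  list(
    results = lapply(configs, stub_result),
    images = lapply(configs, function(cfg)
      list(config_id = cfg$config_id, basis = "umap"))
  )
}

# n generic candidates with ids cand1..candn (distinct single-factor grids
# are not needed when only ids and scores matter).
generic_candidates <- function(n) {
  configs <- lapply(seq_len(n), function(i) {
    structure(list(normalization = "raw", feature_mode = "all",
                   n_pcs = 5L, resolution = 0.5,
                   config_id = paste0("cand", i)),
              class = "pipeline_config")
  })
  stub_candidates(configs)
}

# all permutations of 1..n as rows
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  out
}

scripted_transport <- function(replies) {
  i <- 0L
  calls <- new.env(parent = emptyenv())
  calls$prompts <- character(0)
  f <- function(prompt, image1, image2) {
    i <<- i + 1L
    calls$prompts <- c(calls$prompts, prompt)
    replies[[min(i, length(replies))]]
  }
  attr(f, "calls") <- calls
  f
}

# ---- independent brute-force metric oracles (loop implementations) ----

ari_bf <- function(x, y) {
  tab <- table(x, y)
  n <- length(x)
  sum_comb <- function(v) sum(choose(v, 2))
  sum_ij <- sum(choose(tab, 2))
  a <- sum_comb(rowSums(tab))
  b <- sum_comb(colSums(tab))
  expected <- a * b / choose(n, 2)
  maxi <- (a + b) / 2
  (sum_ij - expected) / (maxi - expected)
}

mi_bf <- function(x, y) {
  n <- length(x)
  ux <- unique(x); uy <- unique(y)
  mi <- 0
  for (a in ux) for (b in uy) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0) mi <- mi + pab * log(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  mi
}

silhouette_bf <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

chi_bf <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); lev <- unique(labels); k <- length(lev)
  grand <- colMeans(x)
  B <- 0; W <- 0
  for (l in lev) {
    xi <- x[labels == l, , drop = FALSE]
    ci <- colMeans(xi)
    B <- B + nrow(xi) * sum((ci - grand)^2)
    for (r in seq_len(nrow(xi))) W <- W + sum((xi[r, ] - ci)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

dbi_bf <- function(x, labels) {
  x <- as.matrix(x)
  lev <- unique(labels); k <- length(lev)
  cent <- lapply(lev, function(l) colMeans(x[labels == l, , drop = FALSE]))
  sc <- vapply(seq_len(k), function(i) {
    xi <- x[labels == lev[i], , drop = FALSE]
    mean(apply(xi, 1, function(r) sqrt(sum((r - cent[[i]])^2))))
  }, 0)
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      rij <- (sc[i] + sc[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, rij)
    }
    total <- total + worst
  }
  total / k
}
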