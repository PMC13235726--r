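test_that("the depth scaling factor is the ratio of mean library sizes", {
  sc <- make_counts(matrix(c(50, 50, 100, 200), 2, 2))
  expect_equal(scaling_factor(sc, sc), 1.0)
  xen <- make_counts(matrix(c(10, 10, 15, 5), 2, 2))
  expect_equal(scaling_factor(sc, xen), 20 / 200)
  expect_equal(scaling_factor(make_counts(matrix(10, 1, 1)),
                              make_counts(matrix(30, 1, 1))), 3.0)
  expect_error(scaling_factor(sc, make_counts(matrix(0L, 2, 2))), "zero mean")
})

test_that("downsampling boundary cases are exact", {
  x <- c(4L, 0L, 6L)
  expect_identical(downsample_cell(x, 10, seed = 1), x)
  expect_identical(downsample_cell(x, 0, seed = 1), c(0L, 0L, 0L))
  expect_error(downsample_cell(x, 11), "exceeds")
  expect_error(downsample_cell(c(-1, 2), 1), "non-negative")
  expect_identical(downsample_cell(x, 5, seed = 42), downsample_cell(x, 5, seed = 42))
})

test_that("downsampling totals are exact and entries never exceed inputs", {
  withr::with_seed(2, {
    for (rep in 1:50) {
      x <- rpois(20, 3)
      t <- sample(0:sum(x), 1)
      y <- downsample_cell(x, t)
      expect_equal(sum(y), t)
      expect_true(all(y <= x))
      expect_true(all(y >= 0))
    }
  })
})

test_that("downsampling follows the multivariate hypergeometric distribution", {
  # input [4, 0, 6], draw 5: first-gene count is Hypergeometric(4, 6, 5);
  # enumerate its pmf exactly and chi-square the empirical counts
  n_draws <- 20000
  draws <- withr::with_seed(11, {
    vapply(seq_len(n_draws), function(i) downsample_cell(c(4L, 0L, 6L), 5L), integer(3))
  })
  expect_true(all(colSums(draws) == 5))
  expect_true(all(draws[2, ] == 0))
  expect_true(all(draws[1, ] <= 4) && all(draws[3, ] <= 6))
  support <- 0:4
  pmf <- dhyper(support, 4, 6, 5)
  obs <- tabulate(draws[1, ] + 1L, nbins = 5)
  chisq <- sum((obs - n_draws * pmf)^2 / (n_draws * pmf))
  pval <- pchisq(chisq, df = length(support) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("simulating from an identical pair is the identity", {
  sc <- random_counts(30, 15, lambda = 5, seed = 3)
  out <- simulate_xenium(sc, sc, seed = 1)
  expect_equal(as.matrix(out$counts$counts), as.matrix(sc$counts))
  expect_equal(out$spec$scaling_factor, 1.0)
  expect_equal(out$spec$per_cell_targets, as.integer(unname(Matrix::colSums(sc$counts))))
})

test_that("simulation restricts to shared genes and inherits labels unchanged", {
  sim <- generate_synthetic_scenario(n_cells = 150, n_genes = 400, n_types = 2,
                                     seed = 4)
  out <- simulate_xenium(sim$sc, sim$xen, seed = 9)
  expect_setequal(out$counts$gene_ids, intersect(sim$sc$gene_ids, sim$xen$gene_ids))
  expect_identical(out$counts$labels, sim$sc$labels)
  expect_identical(out$counts$cell_ids, sim$sc$cell_ids)
  expect_error(simulate_xenium(sim$sc, make_counts(matrix(1, 1, 1,
    dimnames = list("nope", "c1")))), "shared")
})

test_that("a deeper-than-source reference clamps targets with a warning", {
  sc <- make_counts(matrix(c(5L, 5L), 1, 2, dimnames = list("g1", c("a", "b"))))
  xen <- make_counts(matrix(c(30L, 30L), 1, 2, dimnames = list("g1", c("x", "y"))))
  expect_warning(out <- simulate_xenium(sc, xen, seed = 1), "clamped")
  expect_equal(as.vector(out$counts$counts), c(5, 5))
})

test_that("cell filter thresholds are applied and presets are nested", {
  withr::with_seed(6, {
    m <- matrix(rpois(100 * 80, 5), 100, 80)
    m[, 1:15] <- matrix(rpois(100 * 15, 0.4), 100, 15)   # very shallow cells
    m[, 16:30] <- matrix(rpois(100 * 15, 2), 100, 15)    # mid-depth cells
  })
  cm <- make_counts(m)
  kept <- lapply(c("lenient", "medium", "strict"), function(s) {
    apply_cell_filter(cm, s)$cell_ids
  })
  expect_true(all(kept[[3]] %in% kept[[2]]))
  expect_true(all(kept[[2]] %in% kept[[1]]))
  # one cell just under the lenient library threshold is removed
  m2 <- matrix(3L, 20, 3, dimnames = list(paste0("g", 1:20), c("a", "b", "low")))
  m2[, 3] <- rep(c(2L, 0L), each = 10)  # libsize 20 * 2 = 40 < 50
  f <- apply_cell_filter(make_counts(m2), "lenient")
  expect_setequal(f$cell_ids, c("a", "b"))
  expect_equal(attr(f, "n_cells_removed"), 1L)
  # strict filter that removes everything errors
  expect_error(apply_cell_filter(make_counts(m2 * 0L + 1L), "strict"), "removed all")
})

test_that("the synthetic generator respects its preconditions and reproduces bitwise", {
  one <- generate_synthetic_scenario(n_cells = 50, n_genes = 100, n_types = 1, seed = 2)
  expect_equal(unique(one$sc$labels), "type1")
  expect_error(generate_synthetic_scenario(fold_change = 1), "fold_change")
  expect_error(generate_synthetic_scenario(de_fraction = 0), "de_fraction")
  expect_error(generate_synthetic_scenario(n_types = 0), "n_types")
  a <- generate_synthetic_scenario(n_cells = 80, n_genes = 150, seed = 7)
  b <- generate_synthetic_scenario(n_cells = 80, n_genes = 150, seed = 7)
  expect_identical(a, b)
  # reference panel: 20% of genes, ~10% depth
  sim <- generate_synthetic_scenario(n_cells = 300, n_genes = 500, seed = 8)
  expect_equal(nrow(sim$xen$counts), 100)
  depth_ratio <- mean(Matrix::colSums(sim$xen$counts)) /
    mean(Matrix::colSums(sim$sc$counts))
  expect_gt(depth_ratio, 0.05)
  expect_lt(depth_ratio, 0.15)
})

test_that("strong-signal scenarios are recovered by a standard pipeline", {
  sim <- generate_synthetic_scenario(n_cells = 300, n_genes = 800, n_types = 3,
                                     fold_change = 8, seed = 12)
  r <- run_pipeline(sim$sc, pipeline_config("lognorm", "all", 5, 0.5), seed = 1)
  expect_gte(mclust::adjustedRandIndex(r$cluster_labels, sim$sc$labels), 0.9)
})
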