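# a small real pipeline result reused across metric tests
eval_cm <- two_cluster_counts(n_cells = 80, n_genes = 120, seed = 30)
eval_res <- run_pipeline(eval_cm, pipeline_config("lognorm", "all", 5, 0.5), seed = 4)

fake_result <- function(pc, labels) {
  structure(list(config = pipeline_config("raw", "all", 5, 0.5),
                 pc_scores = pc, cluster_labels = labels,
                 n_clusters = length(unique(labels))),
            class = "pipeline_result")
}

test_that("the report carries exactly the five higher-is-better metrics", {
  m <- compute_metrics(eval_res, eval_cm$labels)
  expect_named(m, c("ari", "silhouette", "chi", "one_minus_dbi", "mi"))
  expect_true(all(vapply(m, is.finite, TRUE)))
  # DBI enters negated: reconstructing DBI from the report matches brute force
  dbi <- 1 - m$one_minus_dbi
  expect_equal(dbi, dbi_bf(eval_res$pc_scores, eval_res$cluster_labels),
               tolerance = 1e-10)
})

test_that("perfect clustering gives ARI 1 and the worked ARI example holds", {
  expect_equal(mclust::adjustedRandIndex(eval_res$cluster_labels, eval_cm$labels), 1.0)
  expect_equal(ari_bf(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(mclust::adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
})

test_that("identical balanced binary labelings share ln 2 nats of information", {
  expect_equal(mutual_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), log(2))
  expect_equal(mutual_information(c("a", "a", "b", "b"), c("x", "y", "x", "y")), 0)
})

test_that("MI is non-negative and vanishes for independent labels at large n", {
  withr::with_seed(31, {
    x <- sample(1:3, 10000, replace = TRUE)
    y <- sample(1:4, 10000, replace = TRUE)
  })
  mi <- mutual_information(x, y)
  expect_gte(mi, 0)
  expect_lt(mi, 0.01)
})

test_that("ARI is symmetric, permutation-invariant, and 1 on self-agreement", {
  withr::with_seed(32, {
    for (i in 1:10) {
      x <- sample(1:3, 30, replace = TRUE)
      y <- sample(1:4, 30, replace = TRUE)
      expect_equal(mclust::adjustedRandIndex(x, y), mclust::adjustedRandIndex(y, x))
      relab <- c(9, 7, 8)[x]
      expect_equal(mclust::adjustedRandIndex(relab, y), mclust::adjustedRandIndex(x, y))
      if (length(unique(x)) >= 2) {
        expect_equal(mclust::adjustedRandIndex(x, x), 1.0)
      }
    }
  })
})

test_that("all five metrics agree with brute-force formulas on random instances", {
  withr::with_seed(33, {
    for (i in 1:50) {
      n <- sample(10:50, 1)
      k <- sample(2:4, 1)
      d <- sample(2:5, 1)
      pc <- matrix(rnorm(n * d), n, d)
      labels <- sample(0:(k - 1), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      truth <- sample(letters[1:3], n, replace = TRUE)
      res <- fake_result(pc, labels)
      m <- compute_metrics(res, truth)
      expect_equal(m$ari, ari_bf(labels, truth), tolerance = 1e-10)
      expect_equal(m$mi, mi_bf(labels, truth), tolerance = 1e-10)
      expect_equal(m$silhouette, silhouette_bf(pc, labels), tolerance = 1e-10)
      expect_equal(m$chi, chi_bf(pc, labels), tolerance = 1e-10)
      expect_equal(m$one_minus_dbi, 1 - dbi_bf(pc, labels), tolerance = 1e-10)
    }
  })
})

test_that("single-cluster results flag internal metrics as undefined", {
  withr::with_seed(34, pc <- matrix(rnorm(40), 20, 2))
  res <- fake_result(pc, rep(0L, 20))
  m <- compute_metrics(res, rep(c("a", "b"), 10))
  expect_true(is.na(m$silhouette) && is.na(m$chi) && is.na(m$one_minus_dbi))
  expect_false(is.na(m$ari))
  expect_false(is.na(m$mi))
})

test_that("within-scenario scaling standardizes each row", {
  expect_equal(scale_across_methods(matrix(c(1, 3), 1, 2))[1, ],
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  withr::with_seed(35, m <- matrix(rnorm(6 * 5, sd = 4), 6, 5))
  z <- scale_across_methods(m)
  expect_equal(dim(z), dim(m))
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
  expect_equal(scale_across_methods(z), z, tolerance = 1e-10)  # idempotent
  m2 <- rbind(m, 0)
  rownames(m2) <- paste0("s", 1:7)
  expect_error(scale_across_methods(m2), "s7")
})

test_that("rank of the selected pipeline uses best-rank ties", {
  tab <- data.frame(config_id = c("a", "b", "c"), ari = c(3, 9, 5))
  expect_equal(rank_of_selected("b", tab), 1L)
  expect_equal(rank_of_selected("c", tab), 2L)
  expect_equal(rank_of_selected("a", tab), 3L)
  tab2 <- data.frame(config_id = c("a", "b", "c"), ari = c(9, 9, 5))
  expect_equal(rank_of_selected("a", tab2), 1L)
  expect_equal(rank_of_selected("b", tab2), 1L)
  expect_error(rank_of_selected("zz", tab), "not present")
  tab$sil <- c(NA, 1, 2)
  expect_error(rank_of_selected("a", tab, "sil"), "undefined")
})

test_that("ranking correlation reproduces hand-computed Pearson values", {
  expect_equal(ranking_correlation(1:5, 1:5), 1.0)
  expect_equal(ranking_correlation(1:5, 5:1), -1.0)
  expect_equal(ranking_correlation(c(1, 2, 3, 4), c(2, 1, 3, 4)), 0.8)
  expect_error(ranking_correlation(1:2, 1:2), "length")
  expect_error(ranking_correlation(rep(1, 4), 1:4), "constant")
})

test_that("judge accuracy is 1 for the self-consistent oracle and calibrated when noisy", {
  n <- 10
  cand <- generic_candidates(n)
  vals <- withr::with_seed(36, round(runif(n), 3))
  tab <- data.frame(config_id = paste0("cand", 1:n), ari = vals)
  scores <- setNames(vals, tab$config_id)
  acc <- pairwise_accuracy(cand$results, cand$images, tab,
                           oracle_judge(scores), n_pairs = 20, seed = 1)
  expect_equal(as.numeric(acc), 1.0)
  # noisy judge over many pairs concentrates at p
  accs <- vapply(1:100, function(s) {
    as.numeric(pairwise_accuracy(cand$results, cand$images, tab,
                                 noisy_judge(scores, 0.8, seed = s),
                                 n_pairs = 20, seed = s))
  }, 0)
  expect_gt(mean(accs), 0.78)
  expect_lt(mean(accs), 0.82)
})

test_that("single-step pairs differ in exactly one grid factor", {
  grid <- pipeline_grid(normalization = c("lognorm", "raw"), n_pcs = c(5, 20),
                        resolution = c(0.2, 0.5))
  cand <- stub_candidates(grid)
  n <- length(grid)
  vals <- withr::with_seed(37, runif(n))
  tab <- data.frame(config_id = vapply(grid, `[[`, "", "config_id"), ari = vals)
  acc <- pairwise_accuracy(cand$results, cand$images, tab,
                           oracle_judge(setNames(vals, tab$config_id)),
                           n_pairs = 10, pair_mode = "single_step", seed = 2)
  pairs <- attr(acc, "pairs")
  for (q in seq_len(ncol(pairs))) {
    a <- grid[[pairs[1, q]]]; b <- grid[[pairs[2, q]]]
    ndiff <- sum(a$normalization != b$normalization,
                 a$feature_mode != b$feature_mode,
                 a$n_pcs != b$n_pcs, a$resolution != b$resolution)
    expect_equal(ndiff, 1L)
  }
  expect_equal(as.numeric(acc), 1.0)
  # asking for more pairs than exist reports the achievable count
  expect_error(pairwise_accuracy(cand$results[1:3], cand$images[1:3], tab,
                                 oracle_judge(setNames(vals, tab$config_id)),
                                 n_pairs = 10, seed = 1),
               "3 eligible")
})

test_that("tied metric values are excluded from sampled pairs", {
  n <- 6
  cand <- generic_candidates(n)
  vals <- c(1, 1, 2, 2, 3, 4)  # several exact ties
  tab <- data.frame(config_id = paste0("cand", 1:n), ari = vals)
  acc <- pairwise_accuracy(cand$results, cand$images, tab,
                           oracle_judge(setNames(vals, tab$config_id)),
                           n_pairs = 13, seed = 3)
  pairs <- attr(acc, "pairs")
  expect_equal(ncol(pairs), 13)  # 15 pairs minus 2 tied ones
  for (q in seq_len(ncol(pairs))) {
    expect_false(vals[pairs[1, q]] == vals[pairs[2, q]])
  }
})
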