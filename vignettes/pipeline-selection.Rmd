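---
title: "Selecting single-cell preprocessing pipelines by pairwise visual judging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting single-cell preprocessing pipelines by pairwise visual judging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

The reliability of single-cell analyses hinges on preprocessing: the choice
of normalization, the number of highly variable features, the number of
principal components, and the clustering resolution all change which cell
populations emerge. Defaults tuned on scRNA-seq often transfer poorly to
other data types, notably single-cell-resolution spatial transcriptomics,
where per-cell depth and gene panels differ by an order of magnitude.
Analysts resolve this by eyeballing UMAP or PCA plots from a few candidate
settings — subjective, slow, and irreproducible.

`scjudge` formalizes that visual comparison as an automated selection
procedure. A grid of candidate pipelines is executed, each result is
rendered as a standardized embedding image, and a *judge* — a vision
language model, or a deterministic metric oracle for offline work — picks
the better of two images at a time. A sequential tournament over the
candidates needs only \(N - 1\) comparisons to produce a winner, whose full
preprocessing result is returned for downstream analysis.

## The candidate grid

The default grid crosses four factors, giving
\(6 \times 2 \times 2 \times 3 = 72\) candidates:

* **Normalization** — `sct_analog`, `lognorm`, `clr`, `rc`, `log`, `raw`.
  `lognorm` is depth scaling to a library size of \(10^4\) followed by
  \(\log(1+x)\); `rc` is the depth scaling alone; `log` is \(\log(1+x)\)
  on raw counts; `clr` is the per-cell centered log-ratio with pseudocount 1.
  `sct_analog` computes analytic Pearson residuals of a negative-binomial
  null model with overdispersion \(\theta = 100\) and expectation
  \(\mu_{gc} = (\text{gene total} \times \text{cell total}) / \text{grand total}\),
  clipped at \(\pm\sqrt{n_\text{cells}}\). This is an analytic
  variance-stabilizing transform in the Pearson-residual family; a full
  regularized per-gene NB regression is deliberately not refit, and with a
  large fixed \(\theta\) the residuals behave near-Poisson, which is the
  regime regularized fits reach for most genes anyway.
* **Feature mode** — all \(I\) genes, or the top
  \(a = 2 \times 10^{\lceil \log_{10}(I/2)\rceil - 1}\) genes by a
  variance-stabilized dispersion statistic (loess trend of log variance on
  log mean; standardized values clipped at \(\sqrt{n_\text{cells}}\)). The
  formula keeps roughly the leading order of magnitude: 2 000 genes keep
  200. For degenerate panels (\(I \le 3\)) the raw formula drops below 1,
  so the value is rounded and clamped to \([1, I]\).
* **Number of PCs** — 5 or 20.
* **Resolution** — 0.2, 0.5 or 1 for the modularity clustering.

Enumeration order is fixed (normalization-major, resolution fastest).
Under a noisy judge the tournament outcome can depend on the order in which
candidates are presented, so a documented deterministic order is a
correctness property, not cosmetics.

Downstream of normalization each pipeline applies per-gene z-scoring with
an upper clip at +10, exact PCA (deterministic sign convention: the
largest-magnitude loading of each component is positive), a shared-nearest-
neighbor graph on the retained PCs (k = 20 neighbors including self,
Jaccard edge weights, edges below 1/15 pruned), Louvain modularity
communities at the configured resolution, and a seeded UMAP
(30 neighbors, `min_dist` 0.3). These are the conventional defaults of the
ecosystem this grid mirrors; none are restated per run, all are echoed in
the run manifest. Each stochastic stage draws from a sub-seed hashed from
(master seed, stage, configuration id), so results are reproducible and
independent of execution order.

## Rendering and judging

Images are drawn by primitive rasterization straight into a pixel array —
no fonts, axes, legends or titles — so identical inputs give byte-identical
PNGs on any platform. The judge prompt concerns cluster separation and
boundary clarity; decoration would add noise (and tokens). Up to 30
clusters receive maximally distinct colors; beyond that colors cycle with a
warning. Point draw order is shuffled by seed because points drawn early
can be hidden under later ones; the shuffle removes the systematic part of
that bias. Point size scales as \(\max(1, \text{round}(6 - \log_{10} n))\)
pixels to keep density comparable across dataset sizes.

The LLM judge sends a fixed prompt with both images and accepts only the
replies "1" or "2" (after stripping whitespace and trailing punctuation);
anything else triggers an independent re-prompt, by default at most 10
times — a bounded version of retry-forever, because an unbounded loop has
no place in a library. The transport is a plain function
`(prompt, image1, image2) -> text`, so any vendor API (or a scripted mock)
plugs in without touching the protocol. A five-shot mode queries the judge
five times and takes the majority; `k` must be odd so ties cannot occur.
For PCA-basis runs the word "UMAP" in the prompt is replaced by "PCA"; the
prompt is otherwise identical — this substitution is an assumption, as only
the UMAP wording is canonical.

Two offline backends close the loop without network access:
`oracle_judge()` deterministically prefers the candidate with the higher
value of any supplied score (e.g. ARI against ground truth), and
`noisy_judge()` agrees with that oracle with probability \(p\), drawing
from a private seeded stream. The noisy judge emulates a measured judge
accuracy (a vision LLM is right roughly 80% of the time on such pairs), and
lets the tournament's behavior under imperfect judging be studied
reproducibly.

## The tournament

With a transitive deterministic judge, the sequential \(N-1\) tournament
provably returns the global maximum: the running incumbent loses exactly
when the challenger is better. The test suite verifies this exhaustively
for \(N \le 6\) over all permutations and on 100 random permutations of 72
candidates. Under a noisy judge the winner is a random variable
concentrated near the top; the recorded trace makes every run auditable.

The package also provides a round-robin ranking (all \(N(N-1)/2\) pairs,
ranked by win count, ties broken by grid order). The selection procedure
itself only defines a single winner; a full ranking — needed for
reproducibility analyses via Pearson correlation between repeated runs —
requires the denser design, and the round robin is the simplest one. It is
a documented stand-in, not part of the selection path.

## The spatial-data simulator

To study preprocessing on imaging-based spatial data without a spatial
dataset in hand, the simulator carves one out of an annotated scRNA-seq
sample: restrict to the genes shared with a spatial reference, compute the
depth scaling factor (mean spatial library size over mean scRNA-seq library
size), set each cell's target to `round(libsize * factor)`
(round-half-to-even; the multiplication itself has no canonical rounding
rule, so banker's rounding avoids systematic depth inflation), and
subsample each cell's reads *without replacement* — a multivariate
hypergeometric draw, because a cell's reads are a finite multiset. Targets
are clamped to the cell's own library size when the factor exceeds 1
(subsampling cannot invent reads); a multinomial with-replacement mode
exists behind a flag for sensitivity analysis. Labels are inherited
unchanged, which is what makes the simulated data benchmarkable.

Three preset cell filters (library size ≥ 50/150/300 and detected genes
≥ 10/25/50 for lenient/medium/strict) build scenarios of varying
stringency. The thresholds are this package's own presets, chosen to
produce visibly different scenario sizes on synthetic data.

## Synthetic data: what it does and does not emulate

`generate_synthetic_scenario()` produces clustered negative-binomial
expression: gene base levels from a heavy-tailed log-normal
(`sdlog` 1.3), disjoint per-type marker blocks (default 5% of genes
up-regulated 8-fold), log-normal library sizes (default mean 2 000,
`sdlog` 0.3 — a typical droplet scRNA-seq depth), NB counts with
dispersion `size = 2`, and a companion spatial reference on a random 20%
gene panel at 10% depth, matching the panel-size and depth ratios of
imaging-based platforms relative to scRNA-seq. The defaults are the study
conditions used throughout the tests and the acceptance script; the
600-cell, 2 000-gene, 3-type, fold-change-8 scenario is deliberately
strong-signal so that a rank-1 selection is the correct outcome, and the
problem sizes keep a full 72-pipeline run in the minutes range on one core.

What it does **not** emulate: batch effects, doublets, ambient RNA,
segmentation errors, spatial autocorrelation, or continuous differentiation
trajectories. Passing tests on this generator therefore demonstrate the
*machinery* — protocol exactness, determinism, oracle equivalence,
calibration — not that a visual judge is accurate on real tissue; judge
accuracy on real data is a property of the vision model, measured through
the benchmark functions, not asserted by this package.

## Evaluation suite

`compute_metrics()` reports five higher-is-better quantities: ARI and
mutual information (in nats — the base changes the number, so it is fixed
and stated) against ground-truth labels, plus Silhouette,
Calinski–Harabasz, and 1 − Davies–Bouldin computed from Euclidean
distances in the pipeline's own PC space. DBI is negated so that all five
point the same way. The internal metrics default to the pipeline's own
cluster labels; a flag switches them to the truth partition, because either
reading of "internal quality" is defensible and the two can disagree. With
a single cluster the internal metrics are reported as `NA` rather than
fabricated. Within-scenario comparability across methods uses per-scenario
z-scoring with the sample (n−1) standard deviation.

The benchmark protocol for judge accuracy samples 20 non-tied pairs
(optionally restricted to pairs differing in exactly one grid factor),
asks the judge, and reports the fraction where the judge picked the
higher-metric member. Ties are resampled rather than adjudicated: "better"
is undefined on a tie.

## Numerical and degenerate-input decisions

* `hvg_count()` guards `ceiling(log10(I/2))` with a 1e−9 epsilon so
  floating-point log10 at exact powers of ten cannot bump the exponent;
  tests verify against pure integer arithmetic for all small and sampled
  large panels.
* Constant genes get zero dispersion and standardized-variance ties break
  by gene order, so selection is total and deterministic.
* Cells with zero library size are rejected at load (`read_counts()`)
  rather than dropped silently: downstream normalizations divide by library
  size, and silent dropping would desynchronize labels.
* A clustering that returns a single community is a valid result, not an
  error; its internal metrics are `NA`.
* `n_pcs` must be smaller than both the cell count and the number of
  selected features, checked after feature selection (20 PCs on a 20-gene
  panel is rejected, not silently truncated).

## Limitations

The LLM path is exercised against scripted transports only; live-API
behavior (rate limits, model drift) is outside the package's control and
its tests. The Pearson-residual normalization is an analytic stand-in for
a regularized NB regression fit and will differ from it most for highly
expressed genes. The round-robin ranking is quadratic in candidates and
intended for benchmarking, not routine selection.

## A complete offline run

```{r, eval = FALSE}
library(scjudge)

sim <- generate_synthetic_scenario(n_cells = 300, n_genes = 800,
                                   n_types = 3, seed = 1)
grid <- pipeline_grid(normalization = c("lognorm", "sct_analog"))

# score candidates by ARI against the known labels -> deterministic judge
results <- lapply(grid, function(cfg) run_pipeline(sim$sc, cfg, seed = 1))
scores <- vapply(results, function(r)
  compute_metrics(r, sim$sc$labels)$ari, 0)
names(scores) <- vapply(grid, `[[`, "", "config_id")

fit <- scjudge(sim$sc, grid, backend = oracle_judge(scores), seed = 1)
print(fit)
plot(fit)
```

Swapping `oracle_judge(scores)` for
`llm_judge(transport = my_openai_transport)` turns the same call into the
vision-LLM selection procedure; nothing else changes.
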