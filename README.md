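# scjudge

Automated selection of single-cell preprocessing pipelines by pairwise
visual judging.

## The problem

Clustering results from single-cell RNA-seq and single-cell-resolution
spatial transcriptomics depend heavily on preprocessing choices:
normalization, how many highly variable genes to keep, how many principal
components to retain, and the clustering resolution. Defaults tuned for
scRNA-seq frequently underperform on spatial platforms, whose per-cell
depth and gene panels are an order of magnitude smaller. In practice,
analysts compare UMAP plots from a handful of settings by eye — a
subjective and irreproducible process.

`scjudge` automates that process for analysts of single-cell and spatial
count data. It executes a grid of candidate pipelines, renders each
result's 2-D embedding as a standardized image, and selects a winner with a
sequential pairwise tournament driven by a pluggable visual judge — a
vision language model over a thin transport function, or a deterministic
metric oracle for fully offline, reproducible runs.

## Method

The default grid crosses four factors into 6 × 2 × 2 × 3 = 72 candidate
pipelines:

| factor | values |
| --- | --- |
| normalization | `sct_analog` (NB Pearson residuals, θ = 100), `lognorm`, `clr`, `rc`, `log`, `raw` |
| feature mode | all *I* genes, or *a* = 2 × 10^(⌈log₁₀(I/2)⌉ − 1) top HVGs |
| number of PCs | 5, 20 |
| clustering resolution | 0.2, 0.5, 1 |

Each pipeline runs normalization → feature selection → per-gene scaling →
PCA → shared-nearest-neighbor graph → Louvain clustering → seeded UMAP.
Given *N* candidates, the tournament performs *N* − 1 comparisons:
candidates 1 and 2 meet first, and each subsequent candidate challenges the
current incumbent; the judge sees two images per comparison and must answer
"1" or "2" (invalid replies are re-prompted). With a transitive
deterministic judge the winner is provably the global optimum; under a
noisy judge the recorded trace makes each run auditable. A five-shot
majority mode and a round-robin ranking (for reproducibility analyses) are
included, as are a read-downsampling simulator that emulates shallow
reduced-panel spatial data from annotated scRNA-seq (multivariate
hypergeometric subsampling), preset cell filters, a clustered
negative-binomial synthetic data generator, and a five-metric evaluation
suite (ARI, Silhouette, CHI, 1 − DBI, MI in nats).

## Worked example

A fully offline run on synthetic data, using the ARI against known labels
as a deterministic judge:

```r
library(scjudge)

sim <- generate_synthetic_scenario(n_cells = 300, n_genes = 800,
                                   n_types = 3, seed = 1)
grid <- pipeline_grid(normalization = c("lognorm", "sct_analog"))

results <- lapply(grid, function(cfg) run_pipeline(sim$sc, cfg, seed = 1))
scores <- vapply(results, function(r)
  compute_metrics(r, sim$sc$labels)$ari, 0)
names(scores) <- vapply(grid, `[[`, "", "config_id")

fit <- scjudge(sim$sc, grid, backend = oracle_judge(scores), seed = 1)
print(fit)
#> Pipeline selection by pairwise visual tournament
#>   candidates : 24 (basis: umap, judge: oracle)
#>   comparisons: 23
#>   winner     : lognorm|all|5|0.2 (3 clusters)

compute_metrics(fit$winner, sim$sc$labels)
#> metric_report: ARI 1.000 | silhouette 0.547 | CHI 338.8 | 1-DBI 0.288 | MI 1.099 nats
```

The 24-candidate grid needed 23 comparisons; the selected pipeline
(log-normalization, all genes, 5 PCs, resolution 0.2) recovers the three
simulated cell types exactly (ARI 1.0; MI = ln 3 ≈ 1.099 nats means the
clustering carries all the label information). `plot(fit)` draws the
winning embedding; `summary(fit, truth_labels = ...)` tabulates every
candidate. Swapping the oracle for
`llm_judge(transport = your_api_function)` runs the same selection with a
vision LLM; the transport is any function `(prompt, image1, image2) ->
reply text`.

See the vignette (`vignettes/pipeline-selection.Rmd`) for the model
details, parameter meanings and design decisions.

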