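# apcc — affinity propagation consensus clustering for time-course expression

`apcc` clusters gene expression time series — microarray or RNA-seq log-ratio
profiles measured over a handful of time points — **without asking for the
number of clusters K**. It is aimed at the classic short-time-course setting
(cell cycle, sporulation, stress response: 7–20 time points, hundreds of
genes) where distance-based methods are unstable and model-based methods need
K up front.

## The method

Given profiles G_1, …, G_n on τ time points:

1. **Spline resampling.** Each profile is interpolated with a not-a-knot
   cubic spline and one point is inserted at the temporal midpoint of every
   interval, giving a working grid of p = 2τ − 1 points (33 for τ = 17, 13
   for τ = 7).
2. **Windowed affinity propagation.** For every window size w in
   ⌊p/2⌋ … ⌊3p/4⌋ and every contiguous window of that size (p − w + 1 of
   them), the Pearson correlation matrix

   r_ij = Corr(G_i, G_j | window)

   is clustered by affinity propagation (Frey–Dueck message passing,
   preference = median pairwise similarity, damping 0.9, ≤ 1000 iterations).
   Each run casts one binary co-cluster *vote* per gene pair. For series
   shorter than 10 points, random w-of-τ time-point subsets can replace the
   sliding windows (`extended = TRUE`).
3. **Gene-relativity graph.** Votes are averaged per window size and then
   across sizes into the relativity matrix R, with R_ij the estimated
   probability that genes i and j belong together. R is thresholded at
   σ = 0.50, 0.51, …, 0.80; connected components of each binary graph are
   the candidate partitions.
4. **Selection and refinement.** The σ maximizing the Silhouette index of
   its (pre-refinement) partition wins, ties to the smallest σ. Clusters
   smaller than φ are then merged into major clusters: a singleton joins the
   cluster of its highest-relativity partner (if that relativity ≥ 0.5); a
   larger sub-cluster joins the major cluster whose mean profile it
   correlates with best (if that correlation ≥ 0).

External validation (adjusted Rand index, pair sensitivity/specificity,
Jaccard, Minkowski) and internal validation (Silhouette, Dunn,
Davies–Bouldin) are built in.

## Worked example

Simulate 100 genes in 5 phase-shifted sinusoidal clusters over 17 time
points (two expression cycles, noise SD 0.3), then cluster:

```r
library(apcc)
sim <- synth_timecourse(K = 5, sizes = 20, tau = 17, noise_sd = 0.3, seed = 11)
fit <- apcc(sim$expr, labels = sim$labels, seed = 11)
fit
#> Affinity propagation consensus clustering
#>   100 genes, 33 working time points (126 votes)
#>   selected threshold sigma = 0.50 (Silhouette 0.57224)
#>   final clusters: K = 5 (sizes: 20, 20, 20, 20, 20)
summary(fit)
#> Final partition: K = 5 at sigma = 0.50; cluster sizes 20, 20, 20, 20, 20
#> Votes aggregated into R: 126
#> Validity indices:
#>   ari          1.00000
#>   rand         1.00000
#>   sensitivity  1.00000
#>   specificity  1.00000
#>   jaccard      1.00000
#>   minkowski    0.00000
#>   silhouette   0.57224
#>   dunn         1.14017
#>   dbi          0.62041
```

The 17-point series was doubled to 33 working points, window sizes 16–24
produced 126 affinity-propagation votes, and the partition at the selected
threshold recovers the planted 5-cluster structure exactly (ARI = 1; the
Silhouette of 0.57 reflects the noise level, not the label accuracy).
`fitted(fit)` returns the cluster mean profiles, `plot(fit)` the Silhouette
curve over the threshold grid, and `predict(fit, newdata)` assigns new
profiles to the fitted clusters.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/apcc simulate --out sim --k 5 --size 20 --tau 17 --seed 11
Rscript inst/cli/apcc cluster sim_expression.tsv --labels sim_labels.tsv --out run --seed 11
Rscript inst/cli/apcc validate run_partition.tsv --labels sim_labels.tsv
```

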