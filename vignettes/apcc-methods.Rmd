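---
title: "Consensus clustering of expression time courses with windowed affinity propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus clustering of expression time courses with windowed affinity propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcc)
```

## The problem

Short expression time courses — a few hundred genes measured at 7 to 20
time points — carry their signal in profile *shape*: when a gene peaks,
when it switches off. Clustering them with a single global distance throws
two things away: the temporal ordering of the measurements, and the fact
that co-regulation may hold on a sub-interval only. `apcc` addresses both
by clustering many overlapping time windows separately and letting the
window-level results vote.

A second difficulty is K. Most workhorse algorithms need the number of
clusters as input; for an unannotated time course there is no honest way to
supply it. Affinity propagation sidesteps this: every gene is a potential
exemplar, and the preference value (here the median pairwise similarity)
lets a moderate number of exemplars emerge on its own.

## The pipeline, step by step

**1. Spline resampling.** Each profile is fitted with an interpolating
cubic spline with not-a-knot end conditions and evaluated at the temporal
midpoint of every interval, so τ observed points become p = 2τ − 1 working
points. Rationale for the choices here:

* *Interpolation, not smoothing*: observed values are preserved exactly
  (pass-through at the knots is tested to 1e−9); the inserted points only
  densify the grid so that more and finer windows exist.
* *Not-a-knot boundary*: the standard default for interpolating splines
  when no end derivatives are known; it reproduces cubic polynomials
  exactly and avoids inventing boundary behaviour. The solver builds the
  tridiagonal moment system directly, since no installed spline routine
  exposes this boundary condition.
* *Temporal midpoints, not index midpoints*: real designs are irregular
  (e.g. sampling at 0, 0.5, 2, 5, 7, 9, 11 h); the midpoint of each real
  time interval is where the spline estimate is most trustworthy. On
  uniform grids the two conventions coincide.
* Resampling needs at least 4 points and is a flag (`interpolate = FALSE`
  keeps the original grid), since very dense series gain nothing from it.

**2. Window features and similarity.** All contiguous windows of sizes
w = ⌊p/2⌋ … ⌊3p/4⌋ are enumerated (p − w + 1 windows per size). Below that
range the per-window clusterings become unstable and inject bad votes;
above it too few windows remain to average over. Within a window,
similarity is the Pearson correlation of the two genes' values restricted
to the window — scale- and offset-free, which matches how co-expression is
read in practice. A profile that is flat across a window has an undefined
correlation there; it is assigned the neutral similarity 0 (a flat segment
is evidence of nothing), while self-similarity stays 1.

For very short series (τ < 10) the number of windows is tiny, so an
extended mode replaces contiguous windows with random w-of-τ time-point
subsets. The subset universe grows as C(τ, w), so draws are capped
(`max_subsets`, default 200 per size) and seeded; when C(τ, w) is within
the cap the enumeration is exhaustive and deterministic.

**3. Affinity propagation per window.** Standard responsibility and
availability message passing with damping 0.9, convergence declared after
100 sweeps with an unchanged exemplar set, hard cap 1000 sweeps.
Non-convergence is a warning, not an error — the current exemplar estimate
still casts a usable vote, and single stubborn windows should not kill a
126-window run. A seeded jitter of relative size 1e−13 breaks exact
similarity ties that otherwise sustain message oscillation; it is far below
any data-driven similarity difference, and determinism is preserved because
the jitter derives from the run's seed (each window gets a seed derived
deterministically from the global one, so window-level parallelism could
never change results).

**4. Votes, relativity, partitioning.** Each window's labelling becomes a
binary co-cluster matrix; votes are averaged within each window size and
then equally across sizes. Equal per-size weighting is deliberate even
though sizes contribute different window counts: each size probes a
different temporal scale, and the aggregate should not be dominated by the
small sizes that have the most windows (a vote-weighted mean is available
but off by default). The aggregated matrix R holds empirical co-cluster
probabilities; it is symmetric with unit diagonal by construction and is
accumulated as running sums, never materializing the individual votes.

Thresholding R at σ and taking connected components (iterative depth-first
search, components numbered by first gene in file order for determinism)
yields one candidate partition per σ on the grid 0.50, 0.51, …, 0.80 — 31
partitions. σ below 0.5 is refused: an edge then contradicts the majority
of votes. Because lowering σ only adds edges, the partitions are nested
along the grid, which is tested as an invariant.

**5. Threshold selection.** The winning σ maximizes the Silhouette index
of the *initial* partitions; refinement is excluded from the selection
because merge decisions near the φ boundary are less stable than the vote
fractions themselves. Exact ties go to the smallest σ, i.e. the most
conservative graph. If every grid partition is trivial (K = 1 or K = n)
selection fails loudly with guidance rather than returning an arbitrary σ.

**6. Refinement.** Clusters below φ genes are minor. Singletons join the
cluster of their highest-relativity partner unless even that relativity is
below 0.5 (then they survive — forcing them in would contradict the votes);
multi-gene sub-clusters join the major cluster whose mean working profile
they correlate with best, unless even the best correlation is negative.
Sub-clusters are processed smallest-first (ties by cluster index) so that
the least-supported clusters move first; each merge reduces the cluster
count, so at most L − 1 productive iterations occur and the 500-iteration
cap is a pure safety net. Kept remnants are terminal: they are not
re-examined unless a later merge changes their membership, which makes
refinement idempotent (tested). When no major cluster exists, multi-gene
sub-clusters are all kept — the merge rules presuppose somewhere to merge
into.

φ defaults to `max(2, ceiling(0.01 n))`: singletons are always minor, and
no cluster below 1% of the genes is allowed to stand unexamined. The value
is deliberately conservative and overridable.

## Validity indices

External indices are computed from the pair-confusion counts (TP, FP, FN,
TN over all gene pairs), derived from contingency sums and verified against
explicit pair enumeration in the tests: adjusted Rand (chance-corrected),
plain Rand, sensitivity TP/(TP+FN), specificity TP/(TP+FP) — note this is
pair *precision*, the convention of the clustering-agreement literature,
not 1 − FPR — Jaccard, and the Minkowski measure sqrt((FP+FN)/(TP+FN)).

Internal indices need a dissimilarity. The default is Euclidean distance on
the working profiles, the conventional choice for Silhouette/Dunn/DBI; a
correlation mode (1 − Pearson) is available to match the pipeline's own
similarity. Dunn uses single-linkage separation over cluster diameter (the
classical form; centroid linkage optional); Davies–Bouldin uses mean
distance to centroid and centroid–centroid separation. Singleton clusters
contribute Silhouette 0 by convention. Degenerate cases (one cluster,
coincident centroids, a reference with no co-clustered pair) are errors,
not silent NAs, except inside the bulk `validity_report()` where DBI may be
NA.

## The synthetic generator

`synth_timecourse()` emulates the structure of annotated cell-cycle data:
K prototype curves, each gene a noisy copy of its cluster's prototype,
standardized per gene. Sinusoid prototypes use K evenly spaced phases over
a period spanning the window twice (two cycles, as in cell-cycle designs);
switch prototypes mimic induction/repression waves for sporulation-like
data. Defaults (K = 5, 20 genes per cluster, τ = 17, noise SD 0.3 on
unit-amplitude prototypes) are the study condition used throughout the
acceptance tests; noise 0.3 on an amplitude-1 sinusoid is a realistic
moderate noise level for normalized microarray log-ratios.

What the generator does *not* emulate: missing values, heteroscedastic or
intensity-dependent noise, outlier arrays, cluster-size imbalance beyond
what `sizes` encodes, and genes belonging to no cluster. Passing the
recovery tests therefore demonstrates correctness of the machinery on
well-posed inputs, not robustness to every artefact of real microarray
data.

## Numerical choices and problem sizes

* All randomness flows from one integer seed; derived per-window seeds stay
  below 2^31.
* The spline system is solved densely; grids here are tiny (p ≤ 40).
* Message passing is O(n²) per sweep in vectorized arithmetic; the test
  and example workloads (n = 100 genes, 126 windows) fit comfortably in a
  few seconds. The recovery checks use n = 100, τ = 17 at noise 0.3, and
  smaller n = 18–30 fixtures for the stage-level properties; oracle
  comparisons run at n ≤ 8 (exhaustive exemplar subsets), n ≤ 10
  (transitive closure) and n ≤ 12 (pair enumeration), where brute force is
  exact and fast.
* Ties: threshold selection breaks SI ties toward the smallest σ;
  refinement breaks size ties by cluster index; AP breaks similarity ties
  by the seeded jitter.

## Known limitations

* Sliding windows presuppose a meaningful temporal ordering; the method is
  not for unordered condition panels.
* The relativity matrix is dense: memory is O(n²), fine for hundreds to a
  few thousand genes, not for whole-transcriptome single-cell matrices.
* The Silhouette-based selection inherits Silhouette's bias toward
  compact, balanced clusters; with very unbalanced planted structure the
  selected σ can differ from the ARI-optimal one.
* Exact reproduction of any particular published run of this family of
  algorithms depends on unstated internals of the affinity propagation
  implementation used there; per-window cluster counts are therefore not
  contract, only the consensus behaviour is.
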