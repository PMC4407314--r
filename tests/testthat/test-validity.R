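make_labels <- function(classes, ids = paste0("g", seq_along(classes))) {
  stats::setNames(as.character(classes), ids)
}

test_that("contingency tables count cluster-by-class co-membership", {
  part <- as_partition(c(1, 1, 1, 2, 2), paste0("g", 1:5))
  same <- make_labels(c("a", "a", "a", "b", "b"))
  tab <- contingency(part, same)
  expect_identical(unname(diag(tab)), c(3L, 2L))
  expect_identical(sum(tab) - sum(diag(tab)), 0L)
  singles <- as_partition(1:5, paste0("g", 1:5))
  expect_true(all(rowSums(contingency(singles, same)) == 1))
  # U = {{1,2,3},{4,5}}, V = {{1,2},{3,4,5}} by direct counting
  v <- make_labels(c("x", "x", "y", "y", "y"))
  tab2 <- contingency(part, v)
  expect_identical(unname(tab2), matrix(c(2L, 0L, 1L, 2L), 2))
  expect_error(contingency(part, make_labels(c("a", "a"), c("g1", "g2"))),
               "missing from the label file")
})

test_that("adjusted Rand is 1 on identical partitions and matches hand arithmetic", {
  part <- as_partition(c(1, 1, 2, 2, 3), paste0("g", 1:5))
  expect_equal(adjusted_rand(part, make_labels(c("u", "u", "v", "v", "w"))), 1)
  # 5-gene worked case: U = {123|45}, V = {12|345}
  u <- as_partition(c(1, 1, 1, 2, 2), paste0("g", 1:5))
  v <- make_labels(c("x", "x", "y", "y", "y"))
  # sum_ij C(nij,2) = C(2,2)+C(1,2)+C(0,2)+C(2,2) = 2; sum_i = 4; sum_j = 4
  # expected = 16/10; ARI = (2 - 1.6) / (4 - 1.6) = 1/6
  expect_equal(adjusted_rand(u, v), 1 / 6, tolerance = 1e-12)
})

test_that("adjusted Rand agrees with mclust and is relabeling-invariant", {
  skip_if_not_installed("mclust")
  set.seed(23)
  for (trial in 1:20) {
    n <- sample(8:30, 1)
    u <- random_partition(n, sample(2:5, 1))
    v <- random_partition(n, sample(2:5, 1))
    part <- as_partition(u, paste0("g", 1:n))
    ours <- adjusted_rand(part, make_labels(v, paste0("g", 1:n)))
    expect_equal(ours, mclust::adjustedRandIndex(u, v), tolerance = 1e-12)
    relab <- as_partition(match(u, sample(unique(u))), paste0("g", 1:n))
    expect_equal(adjusted_rand(relab, make_labels(v, paste0("g", 1:n))), ours,
                 tolerance = 1e-12)
  }
})

test_that("pair confusion via contingency equals explicit pair enumeration", {
  ids4 <- paste0("g", 1:4)
  pc <- pair_confusion(as_partition(rep(1, 4), ids4), make_labels(1:4, ids4))
  expect_identical(unname(pc), c(0, 6, 0, 0))
  part <- as_partition(c(1, 1, 2, 2), ids4)
  pc2 <- pair_confusion(part, make_labels(c("a", "a", "b", "b"), ids4))
  expect_identical(unname(pc2[c("FP", "FN")]), c(0, 0))
  set.seed(31)
  for (trial in 1:30) {
    n <- sample(4:12, 1)
    u <- random_partition(n, 3)
    v <- random_partition(n, 3)
    got <- pair_confusion(as_partition(u, paste0("g", 1:n)),
                          make_labels(v, paste0("g", 1:n)))
    expect_identical(unname(got), unname(oracle_pair_confusion(u, v)))
  }
})

test_that("sensitivity, specificity, Jaccard and Minkowski follow the pair counts", {
  set.seed(37)
  n <- 8
  u <- random_partition(n, 3)
  v <- random_partition(n, 2)
  part <- as_partition(u, paste0("g", 1:n))
  lab <- make_labels(v, paste0("g", 1:n))
  pc <- oracle_pair_confusion(u, v)
  rep <- validity_report(part, labels = lab)
  expect_equal(rep$sensitivity, pc[["TP"]] / (pc[["TP"]] + pc[["FN"]]))
  expect_equal(rep$specificity, pc[["TP"]] / (pc[["TP"]] + pc[["FP"]]))
  expect_equal(rep$jaccard, pc[["TP"]] / (pc[["TP"]] + pc[["FN"]] + pc[["FP"]]))
  expect_equal(rep$minkowski,
               sqrt((pc[["FP"]] + pc[["FN"]]) / (pc[["TP"]] + pc[["FN"]])))
  # identical partitions: Minkowski 0; FP = FN = TP gives sqrt(2)
  same <- pair_confusion(part, make_labels(u, paste0("g", 1:n)))
  expect_equal(minkowski_measure(same), 0)
  # closed form: FP = 2 TP with FN = 0 gives sqrt(2)
  expect_equal(minkowski_measure(c(TP = 3, FP = 6, FN = 0, TN = 10)), sqrt(2))
  expect_error(minkowski_measure(c(TP = 0, FP = 2, FN = 0, TN = 4)),
               "no co-clustered pair")
})

test_that("silhouette matches hand arithmetic and the singleton convention", {
  # 6 points in 1-D, two clusters {0, 1, 2} and {10, 11, 12}
  x <- matrix(c(0, 1, 2, 10, 11, 12), 6, 1)
  rownames(x) <- paste0("g", 1:6)
  part <- as_partition(rep(1:2, each = 3), rownames(x))
  # hand: e.g. a(g1) = mean(1,2) = 1.5, b(g1) = mean(10,11,12) = 11
  s_hand <- mean(c(9.5 / 11, 9 / 10, 7.5 / 9, 7.5 / 9, 9 / 10, 9.5 / 11))
  expect_equal(silhouette_index(x, part), s_hand, tolerance = 1e-12)
  # duplicated profiles, distinct between: SI = 1
  y <- matrix(rep(c(0, 5), each = 3), 6, 1)
  rownames(y) <- paste0("g", 1:6)
  expect_equal(silhouette_index(y, part), 1)
  # two singletons: convention 0
  z <- matrix(c(0, 3), 2, 1, dimnames = list(c("a", "b")))
  expect_equal(silhouette_index(z, as_partition(1:2, c("a", "b"))), 0)
  expect_error(silhouette_index(x, as_partition(rep(1, 6), rownames(x))),
               "single cluster")
})

test_that("silhouette agrees with cluster::silhouette on random data", {
  skip_if_not_installed("cluster")
  set.seed(41)
  for (trial in 1:10) {
    n <- sample(6:20, 1)
    x <- matrix(rnorm(n * 3), n, 3, dimnames = list(paste0("g", 1:n), NULL))
    lab <- random_partition(n, 3)
    if (length(unique(lab)) < 2 || length(unique(lab)) == n) next
    part <- as_partition(lab, rownames(x))
    ref <- mean(cluster::silhouette(part$labels, stats::dist(x))[, "sil_width"])
    expect_equal(silhouette_index(x, part), ref, tolerance = 1e-12)
  }
})

test_that("a duplicated gene never lowers its cluster's silhouette widths", {
  set.seed(43)
  x <- matrix(rnorm(24), 8, 3, dimnames = list(paste0("g", 1:8), NULL))
  lab <- rep(1:2, each = 4)
  D <- as.matrix(dist(x))
  base <- apcc:::silhouette_from_dist(D, lab)
  x2 <- rbind(x, g9 = x[1, ])
  D2 <- as.matrix(dist(x2))
  s2 <- apcc:::silhouette_from_dist(D2, c(lab, 1L))
  expect_gte(s2, base - 1e-12)
})

test_that("Dunn index is scale-invariant and matches enumeration", {
  x <- matrix(c(0, 0.2, 0.4, 9.6, 9.8, 10), 6, 1,
              dimnames = list(paste0("g", 1:6)))
  part <- as_partition(rep(1:2, each = 3), rownames(x))
  di <- dunn_index(x, part)
  expect_equal(di, 9.2 / 0.4, tolerance = 1e-12)  # min gap 9.2, max diameter 0.4
  expect_gt(di, 1)
  expect_equal(dunn_index(x * 7, part), di, tolerance = 1e-12)
  # 3-cluster toy vs brute force over all pairs
  set.seed(47)
  y <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("g", 1:10), NULL))
  lab <- rep(1:3, c(3, 3, 4))
  p3 <- as_partition(lab, rownames(y))
  D <- as.matrix(dist(y))
  diam <- max(sapply(1:3, function(k) max(D[lab == k, lab == k])))
  sep <- min(sapply(1:2, function(i) min(sapply((i + 1):3, function(j)
    min(D[lab == i, lab == j])))))
  expect_equal(dunn_index(y, p3), sep / diam, tolerance = 1e-12)
})

test_that("Davies-Bouldin matches direct evaluation and rewards separation", {
  # two identical-shape, well-separated 1-D clusters
  x <- matrix(c(0, 1, 100, 101), 4, 1, dimnames = list(paste0("g", 1:4)))
  part <- as_partition(rep(1:2, each = 2), rownames(x))
  # dispersions 0.5 each, centroid distance 100 -> DBI = 1/100
  expect_equal(davies_bouldin(x, part), 0.01, tolerance = 1e-12)
  expect_lt(davies_bouldin(x, part), 0.5)
  # 3-cluster toy vs direct arithmetic
  set.seed(53)
  y <- matrix(rnorm(24), 8, 3, dimnames = list(paste0("g", 1:8), NULL))
  lab <- rep(1:3, c(3, 3, 2))
  p3 <- as_partition(lab, rownames(y))
  cent <- t(sapply(1:3, function(k) colMeans(y[lab == k, , drop = FALSE])))
  disp <- sapply(1:3, function(k)
    mean(sqrt(rowSums(sweep(y[lab == k, , drop = FALSE], 2, cent[k, ])^2))))
  want <- mean(sapply(1:3, function(i) max(sapply(setdiff(1:3, i), function(j)
    (disp[i] + disp[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))))))
  expect_equal(davies_bouldin(y, p3), want, tolerance = 1e-12)
  # coincident centroids are refused
  z <- matrix(c(0, 2, 0, 2), 4, 1, dimnames = list(paste0("g", 1:4)))
  expect_error(davies_bouldin(z, as_partition(c(1, 1, 2, 2), rownames(z))),
               "coincident")
})

test_that("mean ARI of independent random partitions is centred at zero", {
  set.seed(59)
  n <- 200
  ids <- paste0("g", 1:n)
  vals <- replicate(1000, {
    u <- as_partition(random_partition(n, 4), ids)
    v <- make_labels(random_partition(n, 3), ids)
    adjusted_rand(u, v)
  })
  expect_lt(abs(mean(vals)), 0.02)
})
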