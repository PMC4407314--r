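test_that("clusters are classified by size against phi", {
  part <- as_partition(rep(1:3, c(10, 3, 1)), paste0("g", 1:14))
  cls <- classify_clusters(part, 5)
  expect_identical(cls$major, 1L)
  expect_identical(cls$sub, c(2L, 3L))
  cls1 <- classify_clusters(part, 1)
  expect_length(cls1$sub, 0)
  expect_error(classify_clusters(part, 14), "minor")
  # random partitions agree with a direct size comparison
  set.seed(11)
  for (trial in 1:10) {
    lab <- random_partition(20, 5)
    p <- as_partition(lab, paste0("g", 1:20))
    phi <- sample(2:6, 1)
    cls <- classify_clusters(p, phi)
    sizes <- tabulate(p$labels, p$K)
    expect_identical(cls$sub, which(sizes < phi))
  }
})

test_that("singleton rule keeps, merges into majors, or chains sub-clusters", {
  ids <- paste0("g", 1:6)
  R <- diag(6)
  # g6 singleton, best partner g1 with relativity 0.4 -> survives
  R[6, 1] <- R[1, 6] <- 0.4
  part <- as_partition(c(1, 1, 1, 2, 2, 3), ids)
  act <- merge_singleton(3, part, R, phi = 3)
  expect_identical(act$action, "keep")
  # relativity 0.8 to a major-cluster gene -> merge into that major
  R[6, 1] <- R[1, 6] <- 0.8
  act <- merge_singleton(3, part, R, phi = 3)
  expect_identical(act$action, "merge-major")
  expect_identical(act$target, 1L)
  # two mutual singletons with relativity 0.6 merge into a still-sub pair
  R2 <- diag(6)
  R2[5, 6] <- R2[6, 5] <- 0.6
  part2 <- as_partition(c(1, 1, 1, 1, 2, 3), ids)
  act2 <- merge_singleton(2, part2, R2, phi = 3)
  expect_identical(act2$action, "merge-sub")
  expect_identical(act2$target, 3L)
  a <- sin(2 * pi * (0:7) / 7)
  x2 <- expression_matrix(rbind(a, a, a, a, -a, -a), ids, 0:7)
  refined <- refine_partition(part2, R2, data = x2, phi = 3)
  expect_identical(unname(refined$labels[5]), unname(refined$labels[6]))
})

test_that("multi-gene rule merges into the best-correlated major unless anticorrelated", {
  fx <- toy_fixture("rule2-anticorrelated")
  act <- merge_multi(3, fx$partition, fx$expr, fx$phi)
  expect_identical(act$action, "keep")
  expect_lt(act$correlation, 0)
  # identical mean -> merged there with correlation 1
  v <- fx$expr$values
  v[9:10, ] <- v[1:2, ]
  x2 <- expression_matrix(v, fx$expr$gene_ids, fx$expr$time_stamps)
  act2 <- merge_multi(3, fx$partition, x2, fx$phi)
  expect_identical(act2$action, "merge")
  expect_identical(act2$target, 1L)
  expect_equal(act2$correlation, 1, tolerance = 1e-12)
  # three majors with hand-built means: argmax checked by direct arithmetic
  t <- 0:5
  means <- rbind(sin(t), cos(t), t / 5)
  v3 <- rbind(means[rep(1:3, each = 3), ], sin(t + 0.3), sin(t + 0.3))
  p3 <- as_partition(rep(1:4, c(3, 3, 3, 2)), paste0("g", 1:11))
  x3 <- expression_matrix(v3, paste0("g", 1:11), t)
  act3 <- merge_multi(4, p3, x3, phi = 3)
  cors <- apply(means, 1, function(m) cor(m, sin(t + 0.3)))
  expect_identical(act3$target, which.max(cors))
})

test_that("refinement reaches the expected fixed point on a planted fixture", {
  # 2 majors + 1 mergeable singleton + 1 anticorrelated pair -> final K = 3
  t <- 0:7
  a <- sin(2 * pi * t / 7)
  b <- sin(2 * pi * t / 7 + 0.6)
  vals <- rbind(a, a, a, a, b, b, b, b, -a, -a, a + 0.01)
  ids <- paste0("g", 1:11)
  x <- expression_matrix(vals, ids, t)
  part <- as_partition(c(rep(1, 4), rep(2, 4), 3, 3, 4), ids)
  R <- diag(11)
  R[11, 1] <- R[1, 11] <- 0.9   # singleton g11 strongly tied to major 1
  refined <- refine_partition(part, R, x, phi = 3)
  expect_identical(refined$K, 3L)
  expect_identical(unname(refined$labels[11]), unname(refined$labels[1]))
  expect_identical(unname(refined$labels[9]), unname(refined$labels[10]))
  expect_false(refined$labels[9] %in% refined$labels[1:8])
})

test_that("refinement conserves genes, never splits majors, and is idempotent", {
  set.seed(17)
  sim <- synth_timecourse(K = 3, sizes = c(8, 8, 8), tau = 9, noise_sd = 0.4,
                          seed = 17)
  r <- resample_double(sim$expr)
  R <- build_relativity(r, seed = 17)
  part <- graph_components(binarize(R, 0.75), rownames(R))
  refined <- refine_partition(part, R, r, phi = 3)
  expect_identical(length(refined$labels), length(part$labels))
  expect_identical(sort(unique(unname(refined$labels))), seq_len(refined$K))
  # majors never shrink: genes sharing a cluster keep sharing one
  same_before <- outer(part$labels, part$labels, "==")
  same_after <- outer(refined$labels, refined$labels, "==")
  expect_true(all(same_after[same_before]))
  again <- refine_partition(refined, R, r, phi = 3)
  expect_identical(unname(again$labels), unname(refined$labels))
})

test_that("partitions without sub-clusters or without merge partners are unchanged", {
  part <- as_partition(rep(1:2, each = 5), paste0("g", 1:10))
  R <- diag(10)
  expect_identical(refine_partition(part, R, NULL, phi = 3)$labels, part$labels)
  # all singletons, all relativities below 0.5: everything survives
  single <- as_partition(1:6, paste0("g", 1:6))
  Rlow <- matrix(0.2, 6, 6); diag(Rlow) <- 1
  ref <- refine_partition(single, Rlow, NULL, phi = 2)
  expect_identical(ref$K, 6L)
})
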