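# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# connected components via boolean transitive closure (matrix powering)
oracle_components <- function(graph) {
  n <- nrow(graph)
  reach <- (graph != 0) | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[reach[i, ]] <- cur
    }
  }
  comp
}

# exhaustive exemplar-subset optimization of the affinity propagation
# objective: sum over items of S(i, nearest exemplar) plus the preference of
# every exemplar. Returns the best partition and the optimality margin.
oracle_ap <- function(S, preference) {
  n <- nrow(S)
  Sp <- S
  diag(Sp) <- preference
  key <- function(y) paste(match(y, unique(y)), collapse = ".")
  best_per_partition <- new.env(hash = TRUE, parent = emptyenv())
  labels_per_partition <- new.env(hash = TRUE, parent = emptyenv())
  for (mask in 1:(2^n - 1)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) != 0)
    y <- ex[max.col(Sp[, ex, drop = FALSE], ties.method = "first")]
    y[ex] <- ex
    val <- sum(Sp[cbind(seq_len(n), y)])
    k <- key(y)
    if (is.null(best_per_partition[[k]]) || val > best_per_partition[[k]]) {
      best_per_partition[[k]] <- val
      labels_per_partition[[k]] <- y
    }
  }
  keys <- ls(best_per_partition)
  vals <- vapply(keys, function(k) best_per_partition[[k]], numeric(1))
  ord <- order(vals, decreasing = TRUE)
  # margin between the best and the best *distinct co-cluster structure*
  margin <- if (length(ord) > 1) vals[ord[1]] - vals[ord[2]] else Inf
  list(labels = labels_per_partition[[keys[ord[1]]]], margin = margin)
}

# all-pairs enumeration of the pair-confusion counts
oracle_pair_confusion <- function(u, v) {
  n <- length(u)
  counts <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    su <- u[i] == u[j]; sv <- v[i] == v[j]
    key <- if (su && sv) "TP" else if (su) "FP" else if (sv) "FN" else "TN"
    counts[key] <- counts[key] + 1
  }
  counts
}

# similarity matrix with planted blocks, well separated
block_similarity <- function(block_sizes, within = 0.9, between = -0.8,
                             jitter = 0.02) {
  n <- sum(block_sizes)
  lab <- rep(seq_along(block_sizes), block_sizes)
  S <- ifelse(outer(lab, lab, "=="), within, between)
  noise <- matrix(stats::runif(n * n, -jitter, jitter), n, n)
  S <- S + (noise + t(noise)) / 2
  diag(S) <- 0
  list(S = S, labels = lab)
}

random_partition <- function(n, K) sample.int(K, n, replace = TRUE)

# plain numeric matrix without names or vote bookkeeping, for comparisons
strip_votes <- function(m) {
  m <- unclass(m)
  attr(m, "vote_count") <- NULL
  unname(m)
}

# tiny random-but-smooth expression fixture
smooth_expr <- function(n = 5, tau = 8, seed = 1) {
  set.seed(seed)
  t <- seq(0, 2 * pi, length.out = tau)
  vals <- t(sapply(seq_len(n), function(i)
    sin(t * runif(1, 0.5, 2) + runif(1, 0, 2 * pi)) + rnorm(tau, sd = 0.05)))
  expression_matrix(vals, paste0("g", seq_len(n)), t)
}
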