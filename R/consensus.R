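#' Co-cluster adjacency matrix of one clustering
#'
#' One vote: a binary matrix with `m_ij = 1` exactly when items i and j share
#' an exemplar (always including the diagonal). Encodes the equivalence
#' relation induced by a single window's clustering.
#'
#' @param labels exemplar-index vector as returned by [run_ap()].
#' @return Binary symmetric n x n matrix with unit diagonal.
#' @export
adjacency_from_labels <- function(labels) {
  labels <- as.integer(labels)
  if (any(labels[labels] != labels))
    stop("invalid label vector: exemplars must be their own exemplar")
  outer(labels, labels, "==") + 0
}

#' Average the votes of one window size
#'
#' Entrywise mean of the binary adjacency matrices collected from every window
#' of one size; entry (i, j) is the fraction of those windows that placed the
#' two genes together.
#'
#' @param adjacencies non-empty list of equally sized binary matrices.
#' @return A relativity-type matrix (entries in `[0, 1]`, unit diagonal) with
#'   attribute `vote_count` = number of matrices averaged.
#' @export
consensus_for_size <- function(adjacencies) {
  if (!length(adjacencies)) stop("no adjacency matrices to average")
  dims <- vapply(adjacencies, nrow, integer(1))
  if (length(unique(dims)) > 1L) stop("adjacency matrices differ in dimension")
  out <- Reduce(`+`, adjacencies) / length(adjacencies)
  structure(out, vote_count = length(adjacencies))
}

#' Aggregate per-size consensus matrices into the relativity matrix
#'
#' Unweighted mean over window sizes: every size contributes equally even
#' though sizes yield different numbers of windows. An optional vote-weighted
#' mean (weights proportional to each size's window count) is available but
#' off by default.
#'
#' @param per_size non-empty list of per-size consensus matrices (each with a
#'   `vote_count` attribute).
#' @param weights `"equal"` (default) or `"votes"`.
#' @return The aggregated relativity matrix R; entries in `[0, 1]`, unit
#'   diagonal, attribute `vote_count` = total number of votes.
#' @export
aggregate_consensus <- function(per_size, weights = c("equal", "votes")) {
  weights <- match.arg(weights)
  if (!length(per_size)) stop("no consensus matrices to aggregate")
  dims <- vapply(per_size, nrow, integer(1))
  if (length(unique(dims)) > 1L) stop("consensus matrices differ in dimension")
  votes <- vapply(per_size, function(m) {
    v <- attr(m, "vote_count")
    if (is.null(v)) 1L else as.integer(v)
  }, integer(1))
  w <- if (weights == "equal") rep(1, length(per_size)) else votes
  w <- w / sum(w)
  out <- 0
  for (u in seq_along(per_size)) out <- out + w[u] * unclass(per_size[[u]])
  out <- (out + t(out)) / 2
  diag(out) <- 1
  structure(out, vote_count = sum(votes))
}

#' Build the gene-relativity matrix from windowed affinity propagation
#'
#' Runs affinity propagation once per feature window, converts each label
#' vector to a co-cluster vote, averages votes within each window size and
#' then across sizes. Votes are accumulated as running sums, so memory stays
#' O(n^2) regardless of the number of windows.
#'
#' @param x working [expression_matrix()] (resampled grid when interpolation
#'   is on).
#' @param window_range integer `c(low, high)` of window sizes; default
#'   [recommended_window_range()] of the working grid.
#' @param extended use random time-point subsets instead of contiguous
#'   windows (intended for short series).
#' @param max_subsets cap per size in extended mode.
#' @param ap an [ap_config()].
#' @param seed integer; per-window seeds are derived deterministically from it
#'   so window-level parallelism could not change results.
#' @return Relativity matrix R with attributes `vote_count` and dimnames from
#'   the gene ids.
#' @export
build_relativity <- function(x, window_range = NULL, extended = FALSE,
                             max_subsets = 200L, ap = ap_config(), seed = 1L) {
  stopifnot(inherits(x, "apcc_expr"))
  p <- ncol(x$values)
  n <- nrow(x$values)
  if (is.null(window_range)) window_range <- recommended_window_range(p)
  low <- window_range[1]; high <- window_range[2]
  if (low < 2 || high > p || low > high)
    stop("invalid window range (", low, ", ", high, ") for ", p, " time points")
  per_size <- vector("list", high - low + 1L)
  for (s in seq_along(per_size)) {
    w <- low + s - 1L
    wins <- if (extended) subset_windows(p, w, max_subsets,
                                         seed = derive_seed(seed, s, 0L))
            else sliding_windows(p, w)
    acc <- matrix(0, n, n)
    for (u in seq_along(wins)) {
      cm <- window_correlation(x, wins[[u]])
      y <- run_ap(cm, ap, seed = derive_seed(seed, s, u))
      acc <- acc + adjacency_from_labels(y)
    }
    per_size[[s]] <- structure(acc / length(wins), vote_count = length(wins))
  }
  R <- aggregate_consensus(per_size)
  dimnames(R) <- list(x$gene_ids, x$gene_ids)
  R
}

# deterministic per-window seed fan-out, kept within 32-bit integer range
derive_seed <- function(seed, size_index, window_index) {
  (as.numeric(seed) * 7919 + size_index * 1009 + window_index) %% 2147483647
}
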