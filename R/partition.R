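#' Construct a partition object
#'
#' @param labels integer (or factor-like) cluster assignment, one per gene;
#'   renumbered 1..K in order of first appearance.
#' @param gene_ids character identifiers, same length.
#' @param sigma optional relativity threshold that produced the partition.
#' @return An object of class `"apcc_partition"`: list with `labels` (integer
#'   1..K, named by gene id), `gene_ids`, `K`, `sigma`.
#' @export
as_partition <- function(labels, gene_ids = names(labels), sigma = NA_real_) {
  if (!length(labels)) stop("empty partition")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_along(labels))
  if (length(gene_ids) != length(labels))
    stop("labels and gene_ids differ in length")
  lab <- renumber_by_appearance(labels)
  names(lab) <- gene_ids
  structure(list(labels = lab, gene_ids = as.character(gene_ids),
                 K = max(lab), sigma = sigma),
            class = "apcc_partition")
}

renumber_by_appearance <- function(labels) {
  as.integer(match(labels, unique(labels)))
}

#' @export
print.apcc_partition <- function(x, ...) {
  sizes <- tabulate(x$labels, x$K)
  cat(sprintf("Partition of %d genes into %d clusters (sizes: %s)%s\n",
              length(x$labels), x$K, paste(sizes, collapse = ", "),
              if (!is.na(x$sigma)) sprintf(" at sigma = %.2f", x$sigma) else ""))
  invisible(x)
}

#' Threshold the relativity matrix into a binary graph
#'
#' Keeps an (undirected) edge between two genes exactly when their relativity
#' is at least sigma. Thresholds below 0.5 are refused: below that value two
#' genes were together in fewer than half of the votes.
#'
#' @param R relativity matrix (entries in `[0, 1]`, symmetric).
#' @param sigma threshold in `[0.5, 1]`.
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
binarize <- function(R, sigma) {
  if (sigma < 0.5) stop("relativity threshold must be at least 0.5, got ", sigma)
  if (sigma > 1) stop("relativity threshold cannot exceed 1")
  G <- (unclass(R) >= sigma) + 0
  diag(G) <- 0
  G
}

#' Connected components of a binary gene graph
#'
#' Iterative depth-first search over the adjacency matrix. Clusters are
#' numbered by the first-visited gene, i.e. in gene file order, so the result
#' is deterministic.
#'
#' @param graph binary symmetric adjacency matrix (zero/ignored diagonal).
#' @param gene_ids optional identifiers (defaults to the matrix dimnames).
#' @return An `"apcc_partition"` with one cluster per component.
#' @export
graph_components <- function(graph, gene_ids = rownames(graph)) {
  n <- nrow(graph)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    comp[start] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- which(graph[v, ] != 0 & comp == 0L)
      comp[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  as_partition(comp, gene_ids)
}

#' Sweep a grid of relativity thresholds
#'
#' For every sigma on the grid the relativity graph is binarized and split
#' into connected components, giving the initial (pre-refinement) partition
#' for that threshold, scored by the Silhouette index on the working profiles.
#' Partitions with K = 1 or K = n carry an undefined (NA) score.
#'
#' @param R relativity matrix.
#' @param grid strictly increasing thresholds in `[0.5, 1)`; default
#'   `seq(0.50, 0.80, by = 0.01)` (31 values).
#' @param data optional working [expression_matrix()] used to score each
#'   partition; without it scores are NA.
#' @param dissimilarity `"euclidean"` (default) or `"correlation"` profile
#'   dissimilarity for the Silhouette score.
#' @return A list of class `"apcc_sweep"`: `grid`, `partitions` (list of
#'   `"apcc_partition"`), and `metrics` (data.frame with sigma, K, SI).
#' @export
threshold_sweep <- function(R, grid = seq(0.50, 0.80, by = 0.01), data = NULL,
                            dissimilarity = c("euclidean", "correlation")) {
  dissimilarity <- match.arg(dissimilarity)
  if (!length(grid)) stop("empty threshold grid")
  if (any(diff(grid) <= 0)) stop("threshold grid must be strictly increasing")
  if (any(grid < 0.5 | grid >= 1)) stop("thresholds must lie in [0.5, 1)")
  n <- nrow(R)
  parts <- vector("list", length(grid))
  K <- integer(length(grid))
  SI <- rep(NA_real_, length(grid))
  D <- if (!is.null(data)) profile_dissimilarity(data, dissimilarity)
  for (i in seq_along(grid)) {
    part <- graph_components(binarize(R, grid[i]), rownames(R))
    part$sigma <- grid[i]
    parts[[i]] <- part
    K[i] <- part$K
    if (!is.null(D) && part$K > 1L && part$K < n)
      SI[i] <- silhouette_from_dist(D, part$labels)
  }
  structure(list(grid = grid, partitions = parts,
                 metrics = data.frame(sigma = grid, K = K, SI = SI)),
            class = "apcc_sweep")
}

#' Select the threshold with the best Silhouette index
#'
#' The winning sigma maximizes the Silhouette index of the initial partitions
#' (refinement is deliberately excluded from the selection: merging small
#' clusters is less stable than the vote fractions themselves). Exact ties go
#' to the smallest sigma.
#'
#' @param sweep an `"apcc_sweep"` from [threshold_sweep()].
#' @return The selected sigma (single number).
#' @export
select_threshold <- function(sweep) {
  stopifnot(inherits(sweep, "apcc_sweep"))
  SI <- sweep$metrics$SI
  if (all(is.na(SI)))
    stop("Silhouette undefined for every threshold (all partitions trivial: ",
         "K = 1 or K = n). Widen the threshold grid or inspect the ",
         "relativity matrix.")
  sweep$grid[which.max(SI)]  # which.max: first max = smallest sigma on ties
}
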