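#' Affinity propagation consensus clustering of time-course profiles
#'
#' Fits the full pipeline to a gene-by-time expression matrix: (1) optional
#' per-gene standardization and cubic-spline resampling to a doubled time
#' grid; (2) affinity propagation on the Pearson correlation matrix of every
#' sliding window (or random time-point subset), each run casting one
#' co-cluster vote per gene pair; (3) averaging of the votes into the
#' gene-relativity matrix R, thresholding of R over a grid of cutoffs and
#' extraction of connected components as candidate partitions; (4) selection
#' of the cutoff with the best Silhouette index, then merging of minor
#' clusters into major ones. The number of clusters is never supplied; it
#' emerges from the votes.
#'
#' @param x an [expression_matrix()] object, or a path to a delimited table
#'   accepted by [read_expression_table()].
#' @param labels optional named character reference labels (gene id -> class)
#'   for external validation, or a path readable by [read_labels()].
#' @param standardize standardize each gene profile before clustering.
#' @param interpolate resample to the doubled grid first (needs >= 4 time
#'   points); set `FALSE` for short or already dense series.
#' @param window_range integer `c(low, high)` window sizes; default
#'   [recommended_window_range()] on the working grid.
#' @param extended use random time-point subsets instead of sliding windows
#'   (intended for short series, tau < 10).
#' @param max_subsets cap per size in extended mode.
#' @param sigma_grid strictly increasing relativity thresholds in `[0.5, 1)`.
#' @param phi minor-cluster size threshold; default [default_phi()].
#' @param refine apply the merge rules to the selected partition.
#' @param refine_max_iter iteration cap for the refinement (default 500).
#' @param dissimilarity profile dissimilarity for the internal indices and
#'   the threshold selection: `"euclidean"` (default) or `"correlation"`.
#' @param ap an [ap_config()].
#' @param seed single integer governing all randomness (message-passing
#'   tie-break jitter, subset draws).
#'
#' @return An object of class `"apcc"`: a list with elements `partition`
#'   (final `"apcc_partition"`), `initial_partition` (components at the
#'   selected threshold, before refinement), `sigma` (selected threshold),
#'   `K`, `sweep` (the `"apcc_sweep"`), `relativity` (matrix R), `working`
#'   (the working expression matrix), `validity` (index list), `config` and
#'   `call`.
#' @examples
#' sim <- synth_timecourse(K = 3, sizes = 8, tau = 9, noise_sd = 0, seed = 7)
#' fit <- apcc(sim$expr, labels = sim$labels, interpolate = FALSE, seed = 7)
#' fit$K
#' @export
apcc <- function(x, labels = NULL, standardize = FALSE, interpolate = TRUE,
                 window_range = NULL, extended = FALSE, max_subsets = 200L,
                 sigma_grid = seq(0.50, 0.80, by = 0.01), phi = NULL,
                 refine = TRUE, refine_max_iter = 500L,
                 dissimilarity = c("euclidean", "correlation"),
                 ap = ap_config(), seed = 1L) {
  cl <- match.call()
  dissimilarity <- match.arg(dissimilarity)
  if (is.character(x)) x <- read_expression_table(x)
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)))
    labels <- read_labels(labels)
  stopifnot(inherits(x, "apcc_expr"))
  working <- if (standardize) standardize_genes(x) else x
  if (interpolate) working <- resample_double(working)
  if (is.null(window_range))
    window_range <- recommended_window_range(ncol(working$values))
  R <- build_relativity(working, window_range = window_range,
                        extended = extended, max_subsets = max_subsets,
                        ap = ap, seed = seed)
  sweep <- threshold_sweep(R, sigma_grid, data = working,
                           dissimilarity = dissimilarity)
  sigma <- select_threshold(sweep)
  initial <- sweep$partitions[[match(sigma, sweep$grid)]]
  final <- if (refine)
    refine_partition(initial, R, working, phi = phi,
                     max_iterations = refine_max_iter)
  else initial
  final$sigma <- sigma
  validity <- validity_report(final, labels = labels, data = working,
                              dissimilarity = dissimilarity)
  structure(list(partition = final, initial_partition = initial,
                 sigma = sigma, K = final$K, sweep = sweep, relativity = R,
                 working = working, validity = validity,
                 config = list(standardize = standardize,
                               interpolate = interpolate,
                               window_range = window_range,
                               extended = extended, max_subsets = max_subsets,
                               sigma_grid = sigma_grid,
                               phi = if (is.null(phi))
                                 default_phi(nrow(x$values)) else phi,
                               refine = refine,
                               refine_max_iter = refine_max_iter,
                               dissimilarity = dissimilarity, ap = ap,
                               seed = seed),
                 call = cl),
            class = "apcc")
}

#' @export
print.apcc <- function(x, ...) {
  cat("Affinity propagation consensus clustering\n")
  cat(sprintf("  %d genes, %d working time points (%d votes)\n",
              length(x$partition$labels), ncol(x$working$values),
              attr(x$relativity, "vote_count")))
  cat(sprintf("  selected threshold sigma = %.2f (Silhouette %.5f)\n",
              x$sigma, x$sweep$metrics$SI[match(x$sigma, x$sweep$grid)]))
  cat(sprintf("  final clusters: K = %d (sizes: %s)\n", x$K,
              paste(tabulate(x$partition$labels, x$K), collapse = ", ")))
  invisible(x)
}

#' @export
summary.apcc <- function(object, ...) {
  out <- list(K = object$K, sigma = object$sigma,
              sizes = tabulate(object$partition$labels, object$K),
              metrics = object$sweep$metrics, validity = object$validity,
              vote_count = attr(object$relativity, "vote_count"))
  class(out) <- "summary.apcc"
  out
}

#' @export
print.summary.apcc <- function(x, ...) {
  cat(sprintf("Final partition: K = %d at sigma = %.2f; cluster sizes %s\n",
              x$K, x$sigma, paste(x$sizes, collapse = ", ")))
  cat(sprintf("Votes aggregated into R: %d\n", x$vote_count))
  v <- x$validity
  cat("Validity indices:\n")
  for (nm in names(v))
    if (!is.na(v[[nm]])) cat(sprintf("  %-12s %.5f\n", nm, v[[nm]]))
  cat("Threshold sweep (head):\n")
  print(utils::head(x$metrics))
  invisible(x)
}

#' Plot the threshold sweep of a fitted clustering
#'
#' Silhouette index (selection criterion) and cluster count along the
#' relativity-threshold grid, with the selected threshold marked.
#'
#' @param x an `"apcc"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.apcc <- function(x, ...) {
  m <- x$sweep$metrics
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(m$sigma, m$SI, type = "b", pch = 16,
                 xlab = expression(sigma), ylab = "Silhouette index",
                 main = "Threshold selection", ...)
  graphics::abline(v = x$sigma, lty = 2)
  graphics::par(new = TRUE)
  graphics::plot(m$sigma, m$K, type = "s", col = "grey50", axes = FALSE,
                 xlab = "", ylab = "", log = "y")
  graphics::axis(4, col.axis = "grey40")
  graphics::mtext("clusters K", side = 4, line = 2.5, col = "grey40")
  invisible(x)
}

#' Cluster mean profiles of a fitted clustering
#'
#' @param object an `"apcc"` fit.
#' @param ... unused.
#' @return `fitted()` gives the K x p matrix of cluster mean profiles on the
#'   working grid; `residuals()` gives each gene's working profile minus its
#'   cluster mean.
#' @export
fitted.apcc <- function(object, ...) {
  v <- object$working$values
  lab <- object$partition$labels
  do.call(rbind, lapply(seq_len(object$K), function(k)
    colMeans(v[lab == k, , drop = FALSE])))
}

#' @rdname fitted.apcc
#' @export
residuals.apcc <- function(object, ...) {
  object$working$values - fitted(object)[object$partition$labels, , drop = FALSE]
}

#' Assign new profiles to fitted clusters
#'
#' New genes observed on the original time grid are put through the same
#' preprocessing (standardization, spline resampling) and assigned to the
#' cluster whose mean working profile they correlate with best.
#'
#' @param object an `"apcc"` fit.
#' @param newdata an [expression_matrix()] on the original time grid.
#' @param ... unused.
#' @return Integer cluster assignment named by gene id.
#' @export
predict.apcc <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "apcc_expr"))
  w <- if (object$config$standardize) standardize_genes(newdata) else newdata
  if (object$config$interpolate) w <- resample_double(w)
  if (ncol(w$values) != ncol(object$working$values))
    stop("newdata must live on the fit's original time grid")
  centers <- fitted(object)
  sim <- vapply(seq_len(nrow(w$values)), function(i)
    which.max(vapply(seq_len(nrow(centers)), function(k)
      safe_pearson(w$values[i, ], centers[k, ]), numeric(1))), integer(1))
  stats::setNames(sim, w$gene_ids)
}

#' Validate an existing partition against labels and/or data
#'
#' Computes all applicable validity indices for a stored partition without
#' re-running the clustering.
#'
#' @param partition an `"apcc_partition"` or a path readable by
#'   [read_partition()].
#' @param labels optional reference labels or a path for [read_labels()].
#' @param data optional expression table (object or path) for the internal
#'   indices.
#' @param dissimilarity passed to the internal indices.
#' @param internal require the internal indices (error if `data` is absent).
#' @return A validity index list as from [validity_report()].
#' @export
validate_only <- function(partition, labels = NULL, data = NULL,
                          dissimilarity = c("euclidean", "correlation"),
                          internal = FALSE) {
  if (is.character(partition)) partition <- read_partition(partition)
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)))
    labels <- read_labels(labels)
  if (is.character(data)) data <- read_expression_table(data)
  if (internal && is.null(data))
    stop("internal indices need the expression data; supply 'data'")
  validity_report(partition, labels = labels, data = data,
                  dissimilarity = match.arg(dissimilarity))
}
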