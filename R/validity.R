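#' Contingency table between a partition and reference labels
#'
#' Cross-tabulates the clustering U against the a priori classification V:
#' entry (i, j) counts genes in cluster i and class j.
#'
#' @param partition an `"apcc_partition"`.
#' @param labels named character vector (gene id -> class), covering every
#'   gene of the partition.
#' @return Integer matrix with cluster rows and class columns.
#' @export
contingency <- function(partition, labels) {
  stopifnot(inherits(partition, "apcc_partition"))
  missing <- setdiff(partition$gene_ids, names(labels))
  if (length(missing))
    stop("genes missing from the label file: ", paste(missing, collapse = ", "))
  v <- labels[partition$gene_ids]
  unclass(table(cluster = partition$labels, class = v))
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between a clustering and a
#' reference labelling: 1 means identical partitions, values near 0 are
#' expected for independent partitions.
#'
#' @param partition an `"apcc_partition"`, or a precomputed contingency
#'   matrix.
#' @param labels reference labels (ignored when a contingency matrix is
#'   given).
#' @return A single number <= 1.
#' @export
adjusted_rand <- function(partition, labels = NULL) {
  tab <- if (is.matrix(partition)) partition else contingency(partition, labels)
  n <- sum(tab)
  if (n < 2) stop("need at least 2 genes")
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  denom <- (sum_i + sum_j) / 2 - expected
  if (denom == 0) {
    # both partitions trivial: defined as 1 when they agree perfectly
    if (sum_ij == sum_i && sum_ij == sum_j) return(1)
    stop("adjusted Rand undefined: degenerate partitions that do not agree")
  }
  (sum_ij - expected) / denom
}

#' Pair-confusion counts between a clustering and reference labels
#'
#' Over all `choose(n, 2)` gene pairs: TP are together in both U and V, FP
#' together only in U, FN together only in V, TN in neither. Computed from
#' contingency-table sums (identical to explicit pair enumeration).
#'
#' @inheritParams adjusted_rand
#' @return Named numeric vector `c(TP, FP, FN, TN)`.
#' @export
pair_confusion <- function(partition, labels = NULL) {
  tab <- if (is.matrix(partition)) partition else contingency(partition, labels)
  n <- sum(tab)
  TP <- sum(choose(tab, 2))
  FP <- sum(choose(rowSums(tab), 2)) - TP
  FN <- sum(choose(colSums(tab), 2)) - TP
  TN <- choose(n, 2) - TP - FP - FN
  c(TP = TP, FP = FP, FN = FN, TN = TN)
}

#' Minkowski measure of partition disagreement
#'
#' `sqrt((FP + FN) / (TP + FN))`: the disagreement mass relative to the
#' number of co-classified pairs in the reference; 0 for perfect agreement.
#'
#' @param pc pair-confusion counts from [pair_confusion()].
#' @return A single non-negative number.
#' @export
minkowski_measure <- function(pc) {
  if (pc[["TP"]] + pc[["FN"]] == 0)
    stop("Minkowski measure undefined: the reference has no co-clustered pair")
  sqrt((pc[["FP"]] + pc[["FN"]]) / (pc[["TP"]] + pc[["FN"]]))
}

profile_dissimilarity <- function(data, method = c("euclidean", "correlation")) {
  method <- match.arg(method)
  v <- if (inherits(data, "apcc_expr")) data$values else as.matrix(data)
  if (method == "euclidean") as.matrix(stats::dist(v))
  else {
    cm <- suppressWarnings(stats::cor(t(v)))
    cm[is.na(cm)] <- 0
    d <- 1 - cm
    diag(d) <- 0
    d
  }
}

silhouette_from_dist <- function(D, labels) {
  n <- length(labels)
  K <- max(labels)
  sizes <- tabulate(labels, K)
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- labels[i]
    if (sizes[k] == 1L) { s[i] <- 0; next }  # singleton convention
    a <- sum(D[i, labels == k]) / (sizes[k] - 1L)
    b <- min(vapply(seq_len(K)[-k], function(h) mean(D[i, labels == h]),
                    numeric(1)))
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(s)
}

#' Silhouette index of a partition
#'
#' Mean over genes of `(b - a) / max(a, b)` where a is the mean dissimilarity
#' to the gene's own cluster and b the smallest mean dissimilarity to any
#' other cluster. Members of singleton clusters score 0 by convention.
#'
#' @param data working [expression_matrix()] (or plain matrix of profiles).
#' @param partition an `"apcc_partition"` with K >= 2.
#' @param dissimilarity `"euclidean"` (default) or `"correlation"`
#'   (`1 - Pearson`).
#' @return A single number in `[-1, 1]`.
#' @export
silhouette_index <- function(data, partition,
                             dissimilarity = c("euclidean", "correlation")) {
  stopifnot(inherits(partition, "apcc_partition"))
  if (partition$K < 2L)
    stop("Silhouette undefined for a single cluster (no between-cluster term)")
  D <- profile_dissimilarity(data, match.arg(dissimilarity))
  silhouette_from_dist(D, partition$labels)
}

#' Dunn index
#'
#' Smallest between-cluster separation divided by the largest cluster
#' diameter. By default separation is single linkage (minimum pairwise
#' dissimilarity between clusters) and the diameter is the maximum pairwise
#' dissimilarity within a cluster; `linkage = "centroid"` uses
#' centroid-to-centroid separation instead.
#'
#' @inheritParams silhouette_index
#' @param linkage `"single"` (default) or `"centroid"` between-cluster
#'   separation.
#' @return A single non-negative number; larger is better.
#' @export
dunn_index <- function(data, partition,
                       dissimilarity = c("euclidean", "correlation"),
                       linkage = c("single", "centroid")) {
  stopifnot(inherits(partition, "apcc_partition"))
  if (partition$K < 2L) stop("Dunn index needs at least 2 clusters")
  linkage <- match.arg(linkage)
  dissimilarity <- match.arg(dissimilarity)
  v <- if (inherits(data, "apcc_expr")) data$values else as.matrix(data)
  D <- profile_dissimilarity(v, dissimilarity)
  lab <- partition$labels
  K <- partition$K
  diam <- vapply(seq_len(K), function(k) {
    idx <- which(lab == k)
    if (length(idx) < 2L) 0 else max(D[idx, idx])
  }, numeric(1))
  if (max(diam) == 0) {
    sep0 <- min(vapply(seq_len(K - 1L), function(i) {
      min(vapply((i + 1L):K, function(j)
        min(D[lab == i, lab == j, drop = FALSE]), numeric(1)))
    }, numeric(1)))
    if (sep0 == 0) stop("Dunn index undefined: zero diameters and zero separation")
    return(Inf)
  }
  sep <- Inf
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    s <- if (linkage == "single") min(D[lab == i, lab == j, drop = FALSE])
         else {
           ci <- colMeans(v[lab == i, , drop = FALSE])
           cj <- colMeans(v[lab == j, , drop = FALSE])
           sqrt(sum((ci - cj)^2))
         }
    sep <- min(sep, s)
  }
  sep / max(diam)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst ratio `(disp_i + disp_j) / d(c_i, c_j)`,
#' with dispersion the mean Euclidean distance of members to their centroid
#' and d the centroid-to-centroid distance. Smaller values indicate compact,
#' well-separated clusters.
#'
#' @inheritParams silhouette_index
#' @return A single non-negative number; smaller is better.
#' @export
davies_bouldin <- function(data, partition) {
  stopifnot(inherits(partition, "apcc_partition"))
  if (partition$K < 2L) stop("Davies-Bouldin index needs at least 2 clusters")
  v <- if (inherits(data, "apcc_expr")) data$values else as.matrix(data)
  lab <- partition$labels
  K <- partition$K
  cent <- do.call(rbind, lapply(seq_len(K), function(k)
    colMeans(v[lab == k, , drop = FALSE])))
  disp <- vapply(seq_len(K), function(k) {
    idx <- which(lab == k)
    mean(sqrt(rowSums((v[idx, , drop = FALSE] -
                        matrix(cent[k, ], length(idx), ncol(v),
                               byrow = TRUE))^2)))
  }, numeric(1))
  ratios <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) if (i != j) {
    d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
    if (d == 0) stop("Davies-Bouldin undefined: coincident cluster centroids")
    ratios[i, j] <- (disp[i] + disp[j]) / d
  }
  mean(apply(ratios, 1L, max, na.rm = TRUE))
}

#' Full validity report for a partition
#'
#' External indices (adjusted Rand, plain Rand, sensitivity, specificity,
#' Jaccard, Minkowski) when reference labels are supplied; internal indices
#' (Silhouette, Dunn, Davies-Bouldin) when profile data are supplied.
#' "Specificity" here is pair precision TP/(TP+FP), the convention of the
#' pair-counting literature for clustering agreement.
#'
#' @param partition an `"apcc_partition"`.
#' @param labels optional named character reference labels.
#' @param data optional working profiles for the internal indices.
#' @param dissimilarity passed to the internal indices.
#' @return Named list of index values (NA where not computable).
#' @export
validity_report <- function(partition, labels = NULL, data = NULL,
                            dissimilarity = c("euclidean", "correlation")) {
  dissimilarity <- match.arg(dissimilarity)
  out <- list(ari = NA_real_, rand = NA_real_, sensitivity = NA_real_,
              specificity = NA_real_, jaccard = NA_real_,
              minkowski = NA_real_, silhouette = NA_real_, dunn = NA_real_,
              dbi = NA_real_)
  if (!is.null(labels)) {
    tab <- contingency(partition, labels)
    pc <- pair_confusion(tab)
    out$ari <- adjusted_rand(tab)
    out$rand <- (pc[["TP"]] + pc[["TN"]]) / sum(pc)
    out$sensitivity <- if (pc[["TP"]] + pc[["FN"]] > 0)
      pc[["TP"]] / (pc[["TP"]] + pc[["FN"]]) else NA_real_
    out$specificity <- if (pc[["TP"]] + pc[["FP"]] > 0)
      pc[["TP"]] / (pc[["TP"]] + pc[["FP"]]) else NA_real_
    out$jaccard <- pc[["TP"]] / (pc[["TP"]] + pc[["FN"]] + pc[["FP"]])
    out$minkowski <- if (pc[["TP"]] + pc[["FN"]] > 0)
      minkowski_measure(pc) else NA_real_
  }
  if (!is.null(data) && partition$K >= 2L &&
      partition$K < length(partition$labels)) {
    out$silhouette <- silhouette_index(data, partition, dissimilarity)
    out$dunn <- dunn_index(data, partition, dissimilarity)
    out$dbi <- tryCatch(davies_bouldin(data, partition),
                        error = function(e) NA_real_)
  }
  out
}
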