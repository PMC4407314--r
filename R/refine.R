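#' Default minor-cluster size threshold
#'
#' Clusters smaller than phi are "sub-clusters" subject to merging; the
#' default treats singletons and clusters below 1% of the genes as minor.
#'
#' @param n number of genes.
#' @return Integer phi.
#' @export
default_phi <- function(n) max(2L, as.integer(ceiling(0.01 * n)))

#' Split clusters into major and sub-clusters
#'
#' @param partition an `"apcc_partition"`.
#' @param phi positive integer; a cluster with fewer than phi genes is a
#'   sub-cluster.
#' @return List with `phi`, `sizes` (per cluster), `major` and `sub` (cluster
#'   indices).
#' @export
classify_clusters <- function(partition, phi) {
  stopifnot(inherits(partition, "apcc_partition"))
  n <- length(partition$labels)
  if (phi < 1L) stop("phi must be at least 1")
  if (phi >= n)
    stop("phi = ", phi, " with only ", n, " genes would make every cluster minor")
  sizes <- tabulate(partition$labels, partition$K)
  list(phi = as.integer(phi), sizes = sizes,
       major = which(sizes >= phi), sub = which(sizes < phi))
}

safe_pearson <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Merge decision for a singleton sub-cluster
#'
#' Rule for a one-gene cluster C_q with gene g: find the gene h with the
#' highest relativity to g. If that relativity is below 0.5 the singleton
#' survives; if h sits in a major cluster, C_q is merged there; otherwise the
#' two sub-clusters are merged and the new cluster's type is re-checked.
#'
#' @param cluster_id index of the singleton cluster within `partition`.
#' @param partition current `"apcc_partition"`.
#' @param R relativity matrix over the same genes.
#' @param phi minor-cluster threshold.
#' @return List with `action` (`"keep"`, `"merge-major"` or `"merge-sub"`),
#'   `target` cluster index (NA for keep), `partner` gene id and `relativity`.
#' @export
merge_singleton <- function(cluster_id, partition, R, phi) {
  cls <- classify_clusters(partition, phi)
  g <- which(partition$labels == cluster_id)
  if (length(g) != 1L) stop("cluster ", cluster_id, " is not a singleton")
  rel <- unclass(R)[g, ]
  rel[g] <- -Inf
  h_gene <- which.max(rel)
  if (rel[h_gene] < 0.5)
    return(list(action = "keep", target = NA_integer_,
                partner = partition$gene_ids[h_gene],
                relativity = unname(rel[h_gene])))
  target <- unname(partition$labels[h_gene])
  list(action = if (target %in% cls$major) "merge-major" else "merge-sub",
       target = target, partner = partition$gene_ids[h_gene],
       relativity = unname(rel[h_gene]))
}

#' Merge decision for a multi-gene sub-cluster
#'
#' Rule for a sub-cluster C_q with at least two genes: its mean profile is
#' correlated with the mean profile of every major cluster; C_q merges into
#' the best-correlated major cluster unless even the best correlation is
#' negative (or no major cluster exists), in which case it is kept.
#'
#' @param cluster_id index of the sub-cluster within `partition`.
#' @param partition current `"apcc_partition"`.
#' @param data working [expression_matrix()] (or matrix) of the same genes.
#' @param phi minor-cluster threshold.
#' @return List with `action` (`"keep"` or `"merge"`), `target` major cluster
#'   index (NA for keep) and `correlation`.
#' @export
merge_multi <- function(cluster_id, partition, data, phi) {
  cls <- classify_clusters(partition, phi)
  v <- if (inherits(data, "apcc_expr")) data$values else as.matrix(data)
  idx <- which(partition$labels == cluster_id)
  if (length(idx) < 2L) stop("cluster ", cluster_id, " is a singleton; use merge_singleton()")
  if (!length(cls$major))
    return(list(action = "keep", target = NA_integer_, correlation = NA_real_))
  mq <- colMeans(v[idx, , drop = FALSE])
  cors <- vapply(cls$major, function(h)
    safe_pearson(mq, colMeans(v[partition$labels == h, , drop = FALSE])),
    numeric(1))
  best <- which.max(cors)
  if (cors[best] < 0)
    return(list(action = "keep", target = NA_integer_,
                correlation = cors[best]))
  list(action = "merge", target = cls$major[best], correlation = cors[best])
}

#' Refine a partition by merging minor clusters
#'
#' Repeatedly applies the singleton and multi-gene merge rules to the
#' sub-clusters (smallest first, ties by cluster index) until none remains
#' except unmergeable remnants - singletons whose best relativity is below
#' 0.5 and sub-clusters anticorrelated with every major cluster - or the
#' iteration cap is hit. Only whole clusters are merged; genes are never
#' reassigned individually and clusters never split.
#'
#' @param partition initial `"apcc_partition"`.
#' @param R relativity matrix (used by the singleton rule).
#' @param data working [expression_matrix()] (used by the multi-gene rule).
#' @param phi minor-cluster threshold; default [default_phi()].
#' @param max_iterations safety cap on merge iterations (default 500).
#' @return The refined `"apcc_partition"`, clusters renumbered 1..K by first
#'   appearance in gene order.
#' @export
refine_partition <- function(partition, R, data, phi = NULL,
                             max_iterations = 500L) {
  stopifnot(inherits(partition, "apcc_partition"))
  n <- length(partition$labels)
  if (is.null(phi)) phi <- default_phi(n)
  if (phi >= n)
    stop("phi = ", phi, " with only ", n, " genes would make every cluster minor")
  # cluster identity = smallest member gene index; stable across merges
  lab <- vapply(seq_len(n), function(i)
    min(which(partition$labels == partition$labels[i])), integer(1))
  settled <- logical(n)   # indexed by representative gene
  iter <- 0L
  repeat {
    reps <- unique(lab)
    sizes <- vapply(reps, function(r) sum(lab == r), integer(1))
    subs <- reps[sizes < phi & !settled[reps]]
    if (!length(subs)) break
    if (iter >= max_iterations) {
      warning("refinement stopped at the iteration cap (", max_iterations,
              ") with ", length(subs), " sub-cluster(s) left")
      break
    }
    iter <- iter + 1L
    sub_sizes <- sizes[match(subs, reps)]
    q <- subs[order(sub_sizes, match(subs, sort(reps)))][1L]
    cur <- as_partition(lab, partition$gene_ids)
    qid <- cur$labels[which(lab == q)[1L]]
    if (sum(lab == q) == 1L) {
      act <- merge_singleton(qid, cur, R, phi)
      if (act$action == "keep") { settled[q] <- TRUE; next }
      h <- lab[which(cur$labels == act$target)[1L]]
    } else {
      act <- merge_multi(qid, cur, data, phi)
      if (act$action == "keep") { settled[q] <- TRUE; next }
      h <- lab[which(cur$labels == act$target)[1L]]
    }
    newrep <- min(q, h)
    lab[lab == q | lab == h] <- newrep
    settled[c(q, h)] <- FALSE  # merged cluster's type is re-checked
  }
  out <- as_partition(lab, partition$gene_ids, sigma = partition$sigma)
  out
}
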