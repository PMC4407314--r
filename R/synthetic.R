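#' Generate a synthetic time-course dataset with planted clusters
#'
#' Emulates cell-cycle style expression data: K prototype curves are sampled
#' on the time grid and each gene is its cluster's prototype plus independent
#' Gaussian noise, standardized per gene. Two prototype families are
#' available:
#' \describe{
#'   \item{`"sinusoid"`}{phase-shifted sinusoids `sin(2*pi*2*(t - t0)/range +
#'     phase_k)` with K evenly spaced phases; the period spans the sampled
#'     window twice, mimicking genes peaking in different cell-cycle phases
#'     over two cycles.}
#'   \item{`"switch"`}{piecewise on/off prototypes that switch level at K
#'     evenly spaced change points, mimicking developmental induction or
#'     repression waves.}
#' }
#'
#' @param K number of planted clusters.
#' @param sizes genes per cluster (recycled to length K); sum = n.
#' @param tau number of time points (used when `time_stamps` is NULL).
#' @param time_stamps strictly increasing stamps; default `0:(tau-1)`.
#' @param prototype `"sinusoid"` (default) or `"switch"`.
#' @param noise_sd standard deviation of the additive Gaussian noise (>= 0).
#' @param outlier_fraction optional fraction of entries replaced by uniform
#'   outliers on the profile range (default 0).
#' @param seed integer seed; the output is bit-reproducible per seed.
#' @return List with `expr` (an [expression_matrix()]) and `labels` (named
#'   character vector gene id -> planted class `"C1"..."CK"`).
#' @export
synth_timecourse <- function(K = 5L, sizes = 20L, tau = 17L,
                             time_stamps = NULL,
                             prototype = c("sinusoid", "switch"),
                             noise_sd = 0.3, outlier_fraction = 0,
                             seed = 1L) {
  prototype <- match.arg(prototype)
  if (K < 1L) stop("K must be at least 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  sizes <- rep_len(as.integer(sizes), K)
  if (any(sizes < 1L)) stop("every cluster size must be at least 1")
  n <- sum(sizes)
  if (is.null(time_stamps)) time_stamps <- seq_len(tau) - 1
  time_stamps <- as.numeric(time_stamps)
  p <- length(time_stamps)
  t0 <- time_stamps[1]
  rng <- time_stamps[p] - t0
  proto <- matrix(0, K, p)
  for (k in seq_len(K)) {
    proto[k, ] <- if (prototype == "sinusoid") {
      sin(2 * pi * 2 * (time_stamps - t0) / rng + 2 * pi * (k - 1) / K)
    } else {
      cut <- t0 + rng * k / (K + 1)
      ifelse(time_stamps < cut, 1, -1) * (if (k %% 2 == 0) -1 else 1)
    }
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  lab_k <- rep(seq_len(K), sizes)
  vals <- proto[lab_k, , drop = FALSE] +
    matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  if (outlier_fraction > 0) {
    m <- round(outlier_fraction * n * p)
    pos <- sample.int(n * p, m)
    vals[pos] <- stats::runif(m, min(vals), max(vals))
  }
  ids <- sprintf("gene%03d", seq_len(n))
  expr <- standardize_genes(expression_matrix(vals, ids, time_stamps))
  list(expr = expr,
       labels = stats::setNames(paste0("C", lab_k), ids))
}

#' Small hand-constructed fixtures for the pipeline stages
#'
#' A registry of deterministic toy cases used across examples and tests.
#'
#' \describe{
#'   \item{`"two-block"`}{8 genes in 2 clusters of duplicated (noisier copies
#'     of) opposite profiles, with labels.}
#'   \item{`"bridge-0.6"`}{a 6-gene relativity matrix: two tight 0.9-blocks
#'     joined by a single 0.6 bridge edge, so the graph splits in two exactly
#'     when sigma > 0.6.}
#'   \item{`"rule2-anticorrelated"`}{10 genes: two major clusters plus a
#'     2-gene sub-cluster whose mean profile is anticorrelated with both
#'     majors, so the multi-gene merge rule must keep it.}
#' }
#'
#' @param name one of the registered fixture names.
#' @return A list whose elements depend on the fixture (`expr`, `labels`,
#'   `R`, `expected` as applicable).
#' @export
toy_fixture <- function(name) {
  fixtures <- c("two-block", "bridge-0.6", "rule2-anticorrelated")
  if (!name %in% fixtures)
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "))
  switch(name,
    "two-block" = {
      t <- 0:7
      a <- sin(2 * pi * t / 7)
      base <- rbind(a, a, a, a, -a, -a, -a, -a)
      ids <- paste0("g", 1:8)
      list(expr = expression_matrix(base, ids, t),
           labels = stats::setNames(rep(c("up", "down"), each = 4), ids),
           expected_K = 2L)
    },
    "bridge-0.6" = {
      R <- matrix(0, 6, 6)
      R[1:3, 1:3] <- 0.9
      R[4:6, 4:6] <- 0.9
      R[3, 4] <- R[4, 3] <- 0.6
      diag(R) <- 1
      dimnames(R) <- list(paste0("g", 1:6), paste0("g", 1:6))
      list(R = R, split_above = 0.6)
    },
    "rule2-anticorrelated" = {
      t <- 0:7
      a <- sin(2 * pi * t / 7)
      b <- sin(2 * pi * t / 7 + 0.6)  # positively correlated with a
      vals <- rbind(a, a, a, a, b, b, b, b, -a, -a)
      ids <- paste0("g", 1:10)
      part <- as_partition(c(rep(1, 4), rep(2, 4), rep(3, 2)), ids)
      list(expr = expression_matrix(vals, ids, t), partition = part,
           phi = 3L, surviving_cluster = 3L)
    })
}
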