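#' Recommended sliding-window size range
#'
#' For a working grid of p time points (the doubled grid 2*tau - 1 when
#' interpolation is on) the recommended window sizes run from `floor(p/2)` to
#' `floor(3p/4)`: small windows make the per-window clustering unstable, large
#' ones leave too few windows to vote.
#'
#' @param p number of time points on the working grid (>= 4).
#' @return Integer vector `c(low, high)`.
#' @export
recommended_window_range <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 4)
    stop("p must be a single number >= 4")
  c(low = floor(p / 2), high = floor(3 * p / 4))
}

#' Enumerate contiguous sliding windows
#'
#' All windows of size w over p time points: `p - w + 1` windows with starts
#' `1, ..., p - w + 1`, in order.
#'
#' @param p number of time points.
#' @param w window size, `2 <= w <= p`.
#' @return List of integer index vectors, each of length w.
#' @export
sliding_windows <- function(p, w) {
  if (w < 2L) stop("window size must be at least 2")
  if (w > p) stop("window size ", w, " exceeds the number of time points ", p)
  lapply(seq_len(p - w + 1L), function(s) seq.int(s, s + w - 1L))
}

#' Sample random time-point subsets (extended feature mode)
#'
#' For short series the contiguous windows are too few to vote reliably;
#' instead, w-of-tau subsets of time points are used as features. All
#' `choose(tau, w)` subsets are enumerated when that count does not exceed
#' `max_subsets`; otherwise `max_subsets` distinct subsets are drawn uniformly
#' without replacement, reproducibly for a given seed.
#'
#' @param tau number of available time points.
#' @param w subset size, `2 <= w <= tau`.
#' @param max_subsets cap on the number of subsets (default 200).
#' @param seed integer seed for the draw.
#' @return List of strictly increasing integer index vectors of length w.
#' @export
subset_windows <- function(tau, w, max_subsets = 200L, seed = 1L) {
  if (max_subsets < 1L) stop("max_subsets must be at least 1")
  if (w < 2L) stop("subset size must be at least 2")
  if (w > tau) stop("subset size ", w, " exceeds tau = ", tau)
  total <- choose(tau, w)
  if (total <= max_subsets) {
    cmb <- utils::combn(tau, w)
    return(lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", max_subsets)
  k <- 0L
  while (k < max_subsets) {
    s <- sort(sample.int(tau, w))
    key <- paste(s, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      k <- k + 1L
      out[[k]] <- s
    }
  }
  out
}

# seed scoping helpers: set the RNG deterministically, then put the caller's
# .Random.seed back so library code does not disturb the user's stream
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed %% .Machine$integer.max)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Pearson correlation matrix over one feature window
#'
#' Restricts every gene profile to the window's time-point indices and
#' computes all pairwise Pearson correlations. A gene that is flat over the
#' window has no co-expression signal there; its correlations are set to 0
#' (the neutral similarity), with the diagonal kept at exactly 1.
#'
#' @param x an [expression_matrix()] object (typically the resampled grid).
#' @param window integer vector of time-point indices, length >= 2.
#' @return Symmetric n x n correlation matrix with unit diagonal.
#' @export
window_correlation <- function(x, window) {
  stopifnot(inherits(x, "apcc_expr"))
  window <- as.integer(window)
  if (length(window) < 2L) stop("a window needs at least 2 time points")
  if (any(window < 1L | window > ncol(x$values)))
    stop("window indices out of range")
  sub <- t(x$values[, window, drop = FALSE])
  cm <- suppressWarnings(stats::cor(sub))
  cm[is.na(cm)] <- 0
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  dimnames(cm) <- list(x$gene_ids, x$gene_ids)
  cm
}
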