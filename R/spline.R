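# Interpolating cubic spline with not-a-knot end conditions, solved for the
# knot second derivatives (moments) M_i. Interior rows are the classical
# continuity equations; the two end rows impose third-derivative continuity
# across the second and penultimate knots. Needs >= 4 support points.
notaknot_spline <- function(x, y) {
  x <- unname(x); y <- unname(y)
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L)
  h <- diff(x)
  if (any(h <= 0)) stop("time stamps must be strictly increasing")
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i]     <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  # not-a-knot: (M2-M1)/h1 = (M3-M2)/h2 and its mirror at the right end
  A[1, 1:3] <- c(-h[2], h[1] + h[2], -h[1])
  A[n, (n - 2):n] <- c(-h[n - 1], h[n - 2] + h[n - 1], -h[n - 2])
  M <- solve(A, b)
  list(x = x, y = y, h = h, M = M)
}

eval_notaknot <- function(fit, xout) {
  x <- fit$x; y <- fit$y; h <- fit$h; M <- fit$M
  n <- length(x)
  i <- findInterval(xout, x, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i > n - 1L] <- n - 1L
  dl <- x[i + 1L] - xout
  dr <- xout - x[i]
  M[i] * dl^3 / (6 * h[i]) + M[i + 1L] * dr^3 / (6 * h[i]) +
    (y[i] / h[i] - M[i] * h[i] / 6) * dl +
    (y[i + 1L] / h[i] - M[i + 1L] * h[i] / 6) * dr
}

#' Evaluate a gene's spline-interpolated profile
#'
#' Fits an interpolating cubic spline (not-a-knot end conditions) through one
#' gene's time course and evaluates it at arbitrary query times inside the
#' observed range. At the original time stamps the observations are returned
#' exactly; extrapolation is refused.
#'
#' @param x an [expression_matrix()] object with at least 4 time points.
#' @param gene_index row index of the gene to evaluate.
#' @param query_times numeric times within `[min(t), max(t)]`.
#' @return Numeric vector of interpolated values, one per query time.
#' @export
evaluate_spline <- function(x, gene_index, query_times) {
  stopifnot(inherits(x, "apcc_expr"))
  t <- x$time_stamps
  if (length(t) < 4L)
    stop("cubic spline interpolation needs at least 4 time points; ",
         "disable interpolation for shorter series")
  if (any(query_times < t[1] | query_times > t[length(t)]))
    stop("query times outside the observed range [", t[1], ", ",
         t[length(t)], "]: extrapolation is not supported")
  fit <- notaknot_spline(t, x$values[gene_index, ])
  out <- eval_notaknot(fit, query_times)
  # interpolation contract: exact pass-through at the knots
  at <- match(query_times, t)
  hit <- !is.na(at)
  out[hit] <- x$values[gene_index, at[hit]]
  unname(out)
}

#' Double the time grid by spline resampling
#'
#' Inserts one interpolated point at the temporal midpoint of every interval,
#' turning p observed time points into 2p-1. Values at the original stamps are
#' the original observations (interpolation, not smoothing); inserted values
#' come from the per-gene not-a-knot cubic spline.
#'
#' @param x an [expression_matrix()] object with p >= 4 time points.
#' @return An `"apcc_expr"` with `2p-1` time points; `original_mask` flags the
#'   observed columns.
#' @export
resample_double <- function(x) {
  stopifnot(inherits(x, "apcc_expr"))
  t <- x$time_stamps
  p <- length(t)
  if (p < 4L)
    stop("cubic spline resampling needs at least 4 time points (got ", p,
         "); disable interpolation for shorter series")
  mid <- (t[-p] + t[-1]) / 2
  newt <- numeric(2 * p - 1)
  newt[seq(1, 2 * p - 1, by = 2)] <- t
  newt[seq(2, 2 * p - 2, by = 2)] <- mid
  vals <- matrix(0, nrow(x$values), 2 * p - 1)
  for (g in seq_len(nrow(x$values))) {
    fit <- notaknot_spline(t, x$values[g, ])
    vals[g, seq(1, 2 * p - 1, by = 2)] <- x$values[g, ]
    vals[g, seq(2, 2 * p - 2, by = 2)] <- eval_notaknot(fit, mid)
  }
  mask <- rep(c(TRUE, FALSE), length.out = 2 * p - 1)
  expression_matrix(vals, x$gene_ids, newt, original_mask = mask)
}
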