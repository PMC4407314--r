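#' Affinity propagation controls
#'
#' @param damping message damping factor in `[0.5, 1)`; higher values trade
#'   speed for stability of the message passing.
#' @param max_iterations hard cap on message-passing sweeps.
#' @param convergence_window number of consecutive sweeps the exemplar set
#'   must stay unchanged before the run is declared converged.
#' @param preference self-similarity placed on the diagonal; `"median"` (the
#'   default) uses [median_preference()], or give an explicit number.
#' @return A list of class `"apcc_ap_config"`.
#' @export
ap_config <- function(damping = 0.9, max_iterations = 1000L,
                      convergence_window = 100L, preference = "median") {
  if (damping < 0.5 || damping >= 1) stop("damping must be in [0.5, 1)")
  if (convergence_window > max_iterations)
    stop("convergence_window cannot exceed max_iterations")
  structure(list(damping = damping,
                 max_iterations = as.integer(max_iterations),
                 convergence_window = as.integer(convergence_window),
                 preference = preference),
            class = "apcc_ap_config")
}

#' Median preference for affinity propagation
#'
#' The median of the pairwise similarities (each unordered pair counted once,
#' diagonal excluded), the standard choice yielding a moderate number of
#' exemplars.
#'
#' @param S symmetric similarity matrix, n >= 2.
#' @return A single number.
#' @export
median_preference <- function(S) {
  n <- nrow(S)
  if (is.null(n) || n < 2L) stop("need at least 2 items for a preference")
  stats::median(S[upper.tri(S)])
}

#' Cluster by affinity propagation
#'
#' Frey-Dueck message passing on a similarity matrix: responsibilities and
#' availabilities are exchanged with damping until the exemplar set is stable
#' for `convergence_window` sweeps or `max_iterations` is reached. The number
#' of clusters is not an input; it emerges from the preference placed on the
#' diagonal. A tiny seeded jitter (relative magnitude < 1e-12) breaks exact
#' ties that would otherwise let messages oscillate.
#'
#' @param S symmetric numeric similarity matrix (no NAs). The diagonal is
#'   replaced by the preference.
#' @param config an [ap_config()].
#' @param seed integer seed for the tie-breaking jitter.
#' @return Integer vector `y` of length n: `y[i]` is the index of the exemplar
#'   gene assigned to item i, so `y[y] == y` and exemplars satisfy
#'   `y[k] == k`.
#' @export
run_ap <- function(S, config = ap_config(), seed = 1L) {
  S <- unname(as.matrix(S))
  n <- nrow(S)
  if (n == 1L) return(1L)
  if (!isSymmetric(S)) stop("similarity matrix must be symmetric")
  if (anyNA(S)) stop("similarity matrix contains NA")
  pref <- if (identical(config$preference, "median")) median_preference(S)
          else as.numeric(config$preference)
  diag(S) <- pref
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  scale <- max(abs(S), .Machine$double.eps)
  S <- S + matrix(stats::runif(n * n, -1, 1), n, n) * 1e-13 * scale
  lam <- config$damping
  A <- R <- matrix(0, n, n)
  idx <- cbind(seq_len(n), seq_len(n))
  exemplars_prev <- integer(0)
  stable <- 0L
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    # responsibilities
    AS <- A + S
    j1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(seq_len(n), j1)]
    AS[cbind(seq_len(n), j1)] <- -Inf
    j2 <- max.col(AS, ties.method = "first")
    m2 <- AS[cbind(seq_len(n), j2)]
    Rnew <- S - m1
    Rnew[cbind(seq_len(n), j1)] <- S[cbind(seq_len(n), j1)] - m2
    R <- lam * R + (1 - lam) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    Rp[idx] <- R[idx]
    cs <- colSums(Rp)
    Anew <- rep(cs, each = n) - Rp
    dA <- Anew[idx]
    Anew <- pmin(Anew, 0)
    Anew[idx] <- dA
    A <- lam * A + (1 - lam) * Anew
    ex <- which(A[idx] + R[idx] > 0)
    if (length(ex) && identical(ex, exemplars_prev)) {
      stable <- stable + 1L
      if (stable >= config$convergence_window) { converged <- TRUE; break }
    } else {
      stable <- 0L
      exemplars_prev <- ex
    }
  }
  if (!converged)
    warning("affinity propagation did not converge in ", config$max_iterations,
            " iterations; returning the current exemplar estimate")
  ex <- which(A[idx] + R[idx] > 0)
  if (!length(ex)) ex <- which.max(A[idx] + R[idx])
  y <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  y[ex] <- ex
  y
}
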