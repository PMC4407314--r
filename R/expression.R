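#' Construct an expression matrix object
#'
#' Container for a gene-by-time-point expression table: a numeric matrix with
#' one row per gene, one column per time point, unique gene identifiers and
#' strictly increasing time stamps (arbitrary units).
#'
#' @param values numeric matrix, n genes x p time points (log-ratio expression).
#' @param gene_ids character vector of unique gene identifiers, length n.
#'   Defaults to the rownames of `values`.
#' @param time_stamps strictly increasing numeric vector, length p. Defaults to
#'   the column names of `values` parsed as numbers, or `0:(p-1)`.
#' @param original_mask optional logical vector marking which columns are
#'   original observations (used by [resample_double()]).
#'
#' @return An object of class `"apcc_expr"`: a list with elements `values`
#'   (matrix with gene ids as rownames), `gene_ids`, `time_stamps`, and
#'   `original_mask`.
#' @seealso [read_expression_table()], [resample_double()]
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              time_stamps = NULL, original_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (n < 2L) stop("an expression matrix needs at least 2 genes, got ", n)
  if (p < 3L) stop("an expression matrix needs at least 3 time points, got ", p)
  if (is.null(gene_ids)) stop("gene_ids are required (or set rownames on 'values')")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != n) stop("length(gene_ids) must equal nrow(values)")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(time_stamps)) {
    time_stamps <- if (!is.null(colnames(values))) {
      suppressWarnings(parse_time_header(colnames(values)))
    }
    if (is.null(time_stamps) || anyNA(time_stamps)) time_stamps <- seq_len(p) - 1
  }
  time_stamps <- as.numeric(time_stamps)
  if (length(time_stamps) != p) stop("length(time_stamps) must equal ncol(values)")
  if (anyNA(time_stamps) || any(diff(time_stamps) <= 0))
    stop("time_stamps must be strictly increasing")
  if (anyNA(values)) stop("expression values contain missing entries")
  if (is.null(original_mask)) original_mask <- rep(TRUE, p)
  stopifnot(length(original_mask) == p)
  rownames(values) <- gene_ids
  colnames(values) <- format(time_stamps, trim = TRUE)
  structure(list(values = values, gene_ids = gene_ids,
                 time_stamps = time_stamps,
                 original_mask = as.logical(original_mask)),
            class = "apcc_expr")
}

#' @export
print.apcc_expr <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d time points (t in [%g, %g])\n",
              nrow(x$values), ncol(x$values),
              x$time_stamps[1], x$time_stamps[length(x$time_stamps)]))
  invisible(x)
}

#' @export
dim.apcc_expr <- function(x) dim(x$values)

# strip a leading non-numeric prefix such as "t" or "X" from header labels
parse_time_header <- function(labels) {
  as.numeric(sub("^[^0-9+.-]*", "", labels))
}

#' Standardize each gene profile
#'
#' Centres and scales every row to mean 0 and standard deviation 1 across time.
#' Rows with zero variance are left centred at 0 (they carry no profile shape).
#'
#' @param x an [expression_matrix()] object.
#' @return A standardized `"apcc_expr"` object on the same time grid.
#' @export
standardize_genes <- function(x) {
  stopifnot(inherits(x, "apcc_expr"))
  v <- x$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  v <- sweep(v, 1L, mu)
  ok <- sdv > 0
  v[ok, ] <- v[ok, , drop = FALSE] / sdv[ok]
  expression_matrix(v, x$gene_ids, x$time_stamps, x$original_mask)
}
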