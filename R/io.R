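#' Read a gene-by-time expression table from delimited text
#'
#' The first column holds gene identifiers; remaining columns are numeric
#' expression values, one per time point. The delimiter is auto-detected
#' between tab and comma from the first line; anything else must be given
#' explicitly.
#'
#' @param path path to the text file.
#' @param delimiter field separator; `NULL` (default) auto-detects tab/comma.
#' @param header_is_time if `TRUE`, the header labels of the value columns are
#'   parsed as numeric time stamps (a leading non-numeric prefix such as `"t"`
#'   is stripped); otherwise stamps default to `0, 1, ..., p-1`.
#' @param drop_missing rows with missing cells are an error by default; set
#'   `TRUE` to drop such rows with a warning instead.
#' @param standardize if `TRUE`, apply [standardize_genes()] after loading.
#'
#' @return An [expression_matrix()] object; genes and time points keep file
#'   order.
#' @export
read_expression_table <- function(path, delimiter = NULL, header_is_time = FALSE,
                                  drop_missing = FALSE, standardize = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  delimiter <- detect_delimiter(path, delimiter)
  nf <- utils::count.fields(path, sep = delimiter, quote = "", comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L)
    stop("ragged rows: lines have ", paste(unique(nf), collapse = "/"), " fields")
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("need a gene-id column plus at least 3 time points")
  ids <- tab[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(apply(raw, 2L, as.numeric))
  bad <- which(is.na(vals) & !(is.na(raw) | raw %in% c("", "NA")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at gene '%s' (row %d), column %d",
                 raw[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], bad[1, 1], bad[1, 2]))
  }
  miss <- which(apply(is.na(vals), 1L, any))
  if (length(miss)) {
    if (!drop_missing)
      stop("missing values in gene(s): ", paste(ids[miss], collapse = ", "),
           " (use drop_missing = TRUE to drop them)")
    warning("dropping ", length(miss), " gene(s) with missing values: ",
            paste(ids[miss], collapse = ", "))
    vals <- vals[-miss, , drop = FALSE]
    ids <- ids[-miss]
  }
  stamps <- if (header_is_time) {
    ts <- parse_time_header(colnames(tab)[-1L])
    if (anyNA(ts)) stop("header labels could not be parsed as time stamps")
    ts
  } else seq_len(ncol(vals)) - 1
  out <- expression_matrix(vals, ids, stamps)
  if (standardize) out <- standardize_genes(out) else out
}

#' @rdname read_expression_table
#' @param x an [expression_matrix()] object to write.
#' @export
write_expression_table <- function(x, path, delimiter = "\t") {
  stopifnot(inherits(x, "apcc_expr"))
  header <- paste(c("gene", paste0("t", format(x$time_stamps, trim = TRUE))),
                  collapse = delimiter)
  rows <- vapply(seq_along(x$gene_ids), function(i) {
    paste(c(x$gene_ids[i], sprintf("%.17g", x$values[i, ])), collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

detect_delimiter <- function(path, delimiter) {
  if (!is.null(delimiter)) return(delimiter)
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t"
  else if (grepl(",", first)) ","
  else stop("could not auto-detect delimiter (tab or comma); please specify")
}

#' Read a gene-to-class label file
#'
#' Two-column delimited text: gene identifier, class name.
#'
#' @inheritParams read_expression_table
#' @return A named character vector mapping gene id to class.
#' @export
read_labels <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delimiter <- detect_delimiter(path, delimiter)
  tab <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty label file: ", path)
  if (ncol(tab) != 2L) stop("label file must have exactly two columns")
  dup <- tab[[1L]][duplicated(tab[[1L]])]
  if (length(dup)) stop("duplicate gene(s) in label file: ",
                        paste(unique(dup), collapse = ", "))
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Write / read a partition as two-column text
#'
#' Writes `gene_id <TAB> cluster` with clusters renumbered 1..K in order of
#' first appearance.
#'
#' @param partition an `"apcc_partition"` object (see [as_partition()]).
#' @param path output path.
#' @return `write_partition()` returns `path` invisibly; `read_partition()`
#'   returns an `"apcc_partition"`.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "apcc_partition"))
  if (length(partition$labels) == 0L) stop("empty partition")
  lab <- renumber_by_appearance(partition$labels)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines(paste(partition$gene_ids, lab, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path, delimiter = "\t") {
  tab <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = c("character", "integer"),
                           quote = "", comment.char = "")
  as_partition(tab[[2L]], tab[[1L]])
}

#' Write / read a symmetric gene-by-gene matrix
#'
#' Delimited text with a header row and a leading id column; values are
#' written with 17 significant digits so a round trip is value-exact.
#'
#' @param matrix symmetric numeric matrix.
#' @param gene_ids identifiers, one per row/column.
#' @param path output path.
#' @export
write_matrix <- function(matrix, gene_ids, path) {
  if (nrow(matrix) != ncol(matrix)) stop("matrix must be square")
  if (length(gene_ids) != nrow(matrix))
    stop("length(gene_ids) (", length(gene_ids), ") must match matrix dimension (",
         nrow(matrix), ")")
  if (!isSymmetric(unname(matrix))) stop("matrix must be symmetric")
  lines <- c(paste(c("id", gene_ids), collapse = "\t"),
             vapply(seq_len(nrow(matrix)), function(i) {
               paste(c(gene_ids[i], sprintf("%.17g", matrix[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           row.names = 1L, quote = "", comment.char = "")
  m <- as.matrix(tab)
  dimnames(m) <- list(rownames(tab), colnames(tab))
  m
}

#' Write a per-threshold metrics table
#'
#' One row per relativity threshold sigma, with cluster count and validity
#' indices, as tab-separated text.
#'
#' @param metrics data.frame as found in the `sweep` element of an [apcc()] fit.
#' @param path output path.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
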