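#' Construct an expression matrix
#'
#' An expression matrix is a genes x samples numeric matrix with unique row
#' (gene) and column (sample) identifiers and a declared value kind:
#' \code{"counts"} (non-negative integers), \code{"fpkm"}, or
#' \code{"normalized"} (cohort-mean-normalized FPKM, see
#' [mean_normalize()]). Missing values are not permitted; zeros must be
#' explicit.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames and colnames set.
#' @param value_kind one of \code{"counts"}, \code{"fpkm"},
#'   \code{"normalized"}.
#' @return an \code{expr_matrix}: the matrix with its kind attached.
#' @export
expression_matrix <- function(values, value_kind = c("counts", "fpkm", "normalized")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  stop_if_duplicated(rownames(values), "gene")
  stop_if_duplicated(colnames(values), "sample")
  if (anyNA(values))
    stop("missing values are not permitted; use explicit zeros", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  if (value_kind == "counts" && any(values != round(values)))
    stop("counts must be integers", call. = FALSE)
  structure(values, value_kind = value_kind, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              attr(x, "value_kind"), nrow(x), ncol(x)))
  invisible(x)
}

value_kind <- function(x) attr(x, "value_kind")

assert_kind <- function(x, kind) {
  if (!inherits(x, "expr_matrix"))
    stop("expected an expr_matrix (see expression_matrix())", call. = FALSE)
  if (!identical(value_kind(x), kind))
    stop(sprintf("expected value_kind '%s', got '%s'", kind, value_kind(x)), call. = FALSE)
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' Expects genes in rows: first column gene identifiers, header row sample
#' identifiers, numeric body. Use \code{transpose = TRUE} for files stored
#' samples x genes; orientation is never guessed.
#'
#' @param path TSV/CSV file path.
#' @param value_kind declared kind of the stored values.
#' @param sep field separator (default tab).
#' @param transpose set TRUE if the file is samples x genes.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, value_kind = c("counts", "fpkm", "normalized"),
                                   sep = "\t", transpose = FALSE) {
  value_kind <- match.arg(value_kind)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  ids <- trimws(df[[1L]])
  stop_if_duplicated(ids, "gene")
  stop_if_duplicated(trimws(colnames(df)[-1L]), "sample")
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 as.matrix(body)[bad[1L, , drop = FALSE]],
                 ids[bad[1L, 1L]], colnames(body)[bad[1L, 2L]]), call. = FALSE)
  }
  rownames(num) <- ids
  if (transpose) num <- t(num)
  expression_matrix(num, value_kind)
}

#' Write an expression matrix as delimited text
#'
#' @param x an [expression_matrix()].
#' @param path output file.
#' @param sep field separator.
#' @param id_column header for the gene-identifier column.
#' @export
write_expression_matrix <- function(x, path, sep = "\t", id_column = "gene_id") {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert raw counts to FPKM
#'
#' FPKM (fragments per kilobase of transcript per million mapped reads) for
#' gene g in sample s is
#' \deqn{FPKM_{gs} = counts_{gs} \times 10^9 / (N_s \times L_g)}
#' where \eqn{N_s} is the library size (column sum of the counts matrix) and
#' \eqn{L_g} the transcript length in base pairs. Apply any low-count filter
#' before this step: library sizes are column sums of the matrix given here.
#'
#' @param counts an [expression_matrix()] of kind \code{"counts"}.
#' @param lengths data frame with columns \code{gene_id}, \code{length_bp}
#'   (positive integers); every gene in \code{counts} must be present.
#' @return an [expression_matrix()] of kind \code{"fpkm"}.
#' @export
counts_to_fpkm <- function(counts, lengths) {
  assert_kind(counts, "counts")
  stopifnot(is.data.frame(lengths), all(c("gene_id", "length_bp") %in% names(lengths)))
  if (any(lengths$length_bp < 1)) stop("gene lengths must be >= 1 bp", call. = FALSE)
  len <- lengths$length_bp[match(rownames(counts), trimws(lengths$gene_id))]
  if (anyNA(len)) {
    miss <- rownames(counts)[is.na(len)]
    stop(sprintf("missing gene length for: %s",
                 paste(utils::head(miss, 5L), collapse = ", ")), call. = FALSE)
  }
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop(sprintf("zero library size for sample(s): %s",
                 paste(colnames(counts)[lib == 0], collapse = ", ")), call. = FALSE)
  }
  fpkm <- unclass(counts) * 1e9 / outer(len, lib)
  expression_matrix(fpkm, "fpkm")
}

#' Filter genes with insufficient read support
#'
#' Keeps genes with at least \code{min_reads} reads in at least
#' \code{min_samples} samples; the defaults implement the rule of removing
#' transcripts without a minimum of 1 read in at least three samples. The
#' sample set is unchanged.
#'
#' @param counts an [expression_matrix()] of kind \code{"counts"}.
#' @param min_reads minimum read count per qualifying sample.
#' @param min_samples minimum number of qualifying samples.
#' @return the filtered counts matrix.
#' @export
filter_low_expression <- function(counts, min_reads = 1L, min_samples = 3L) {
  assert_kind(counts, "counts")
  if (min_samples > ncol(counts))
    stop(sprintf("min_samples (%d) exceeds number of samples (%d)",
                 min_samples, ncol(counts)), call. = FALSE)
  keep <- rowSums(unclass(counts) >= min_reads) >= min_samples
  expression_matrix(unclass(counts)[keep, , drop = FALSE], "counts")
}
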