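#' Construct a CountMatrix
#'
#' The core container of the package: an integer gene-by-sample count matrix
#' together with a condition label for every sample and a transcript length
#' (bp) for every gene. This is the object every downstream stage (FPKM
#' normalization, differential expression, target classification) consumes.
#'
#' @param counts integer matrix, genes in rows and samples in columns, with
#'   row and column names. Counts must be non-negative and integral.
#' @param condition character vector of condition labels, one per sample
#'   (recycled names from \code{colnames(counts)} if unnamed).
#' @param gene_length positive integer vector of transcript lengths in bp,
#'   one per gene.
#' @return An object of class \code{CountMatrix}: a list with elements
#'   \code{counts}, \code{condition} and \code{gene_length}.
#' @export
count_matrix <- function(counts, condition, gene_length) {
  if (!is.matrix(counts)) stop("'counts' must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have row (gene) and column (sample) names")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  if (length(condition) != ncol(counts))
    stop("one condition label per sample required")
  if (length(gene_length) != nrow(counts))
    stop("one gene length per gene required")
  if (any(gene_length <= 0)) stop("gene lengths must be positive")
  if (is.null(names(condition))) names(condition) <- colnames(counts)
  if (is.null(names(gene_length))) names(gene_length) <- rownames(counts)
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts,
         condition = as.character(condition),
         gene_length = as.integer(gene_length)),
    class = "CountMatrix"
  )
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("conditions:", paste(sprintf("%s (n=%d)", names(table(x$condition)),
                                   table(x$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Write a CountMatrix to a directory of TSV files
#'
#' Persists \code{counts.tsv} (gene_id plus one column per sample),
#' \code{conditions.tsv} (sample_id, condition) and \code{gene_lengths.tsv}
#' (gene_id, length). All plain text, so intermediates stay inspectable.
#'
#' @param x a \code{CountMatrix}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "CountMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts_df <- data.frame(gene_id = rownames(x$counts), x$counts,
                          check.names = FALSE)
  p1 <- file.path(dir, "counts.tsv")
  p2 <- file.path(dir, "conditions.tsv")
  p3 <- file.path(dir, "gene_lengths.tsv")
  utils::write.table(counts_df, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(x$counts), condition = x$condition),
    p2, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = rownames(x$counts), length = x$gene_length),
    p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read a CountMatrix from TSV files
#'
#' Inverse of \code{\link{write_count_matrix}}.
#'
#' @param counts_file counts TSV (gene_id + one column per sample).
#' @param conditions_file sample-to-condition map TSV.
#' @param lengths_file gene length TSV.
#' @return A \code{CountMatrix}.
#' @export
read_count_matrix <- function(counts_file, conditions_file, lengths_file) {
  cdf <- utils::read.table(counts_file, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(m) <- cdf[[1]]
  storage.mode(m) <- "integer"
  cond <- utils::read.table(conditions_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  len <- utils::read.table(lengths_file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  cond_v <- cond$condition[match(colnames(m), cond$sample_id)]
  if (anyNA(cond_v)) stop("samples missing from condition map")
  len_v <- len$length[match(rownames(m), len$gene_id)]
  if (anyNA(len_v)) stop("genes missing from length table")
  count_matrix(m, cond_v, len_v)
}
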