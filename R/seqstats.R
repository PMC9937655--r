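#' Transcript length statistics
#'
#' Computes the descriptive statistics used to characterize an assembled
#' transcriptome: count, mean length, N50, N90 and binned length counts.
#' N50 is the first length L, walking lengths in descending order, at which
#' the cumulative sum of lengths reaches at least 50\% of the total
#' (the standard assembly-stats convention); N90 analogously at 90\%.
#'
#' @param lengths positive integer vector of sequence lengths in bp.
#' @param bin_edges increasing numeric vector of bin left edges; bins are
#'   half-open [lo, hi) with a final open-ended bin from the last edge.
#'   Default matches the 0-1 / 1-2 / 2-3 / >3 kb reporting convention.
#' @return A list of class \code{LengthStats}: \code{n_sequences},
#'   \code{mean_length}, \code{n50}, \code{n90}, \code{bin_counts}.
#' @examples
#' length_stats(c(2, 3, 4, 5, 6))$n50  # 5: 6+5 = 11 >= 10
#' @export
length_stats <- function(lengths, bin_edges = c(0, 1000, 2000, 3000)) {
  if (length(lengths) == 0) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  srt <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(srt))
  total <- cum[length(cum)]
  nX <- function(frac) srt[which(cum >= frac * total)[1]]
  edges <- c(bin_edges, Inf)
  cuts <- cut(lengths, breaks = edges, right = FALSE)
  labs <- c(sprintf("[%g,%g)", utils::head(bin_edges, -1), bin_edges[-1]),
            sprintf(">=%g", bin_edges[length(bin_edges)]))
  bin_counts <- as.integer(table(cuts))
  names(bin_counts) <- labs
  structure(
    list(n_sequences = length(lengths),
         mean_length = mean(lengths),
         n50 = as.integer(nX(0.5)),
         n90 = as.integer(nX(0.9)),
         bin_counts = bin_counts),
    class = "LengthStats")
}

#' @export
print.LengthStats <- function(x, ...) {
  cat(sprintf("%d sequences, mean %.1f bp, N50 %d bp, N90 %d bp\n",
              x$n_sequences, x$mean_length, x$n50, x$n90))
  print(x$bin_counts)
  invisible(x)
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' \code{FPKM[g,s] = counts[g,s] * 1e9 / (library_size[s] * length[g])},
#' where library size is the column sum of the count matrix.
#'
#' @param x a \code{\link{count_matrix}}.
#' @return Numeric matrix of the same dimensions as the counts.
#' @export
fpkm <- function(x) {
  stopifnot(inherits(x, "CountMatrix"))
  lib <- colSums(x$counts)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(x$counts)[lib == 0], collapse = ", "))
  t(t(x$counts) / lib) * 1e9 / x$gene_length
}

#' Read a FASTA file as a DNAStringSet
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet}; sequence names are
#' truncated at the first whitespace and sequences uppercased.
#'
#' @param path FASTA file path.
#' @return A named \code{DNAStringSet}.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))
  Biostrings::DNAStringSet(toupper(as.character(s)))
}

#' Length statistics of a FASTA file
#'
#' @param path FASTA file path.
#' @param ... passed to \code{\link{length_stats}}.
#' @return A \code{LengthStats}.
#' @export
fasta_stats <- function(path, ...) {
  length_stats(Biostrings::width(read_fasta(path)), ...)
}
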