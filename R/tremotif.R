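#' Scan configuration for the DR4 thyroid response element
#'
#' The canonical TRE is a direct repeat of the AGGTCA half-site spaced by
#' four unconstrained bases (DR4): \code{AGGTCANNNNAGGTCA}. Mismatches are
#' budgeted only at the non-N (half-site) positions; the spacer matches
#' anything.
#'
#' @param pattern degenerate pattern over \{A,C,G,T,N\}.
#' @param max_mismatch mismatch budget at non-N positions (default 4).
#' @param window_bp promoter window length to scan (default 5000); longer
#'   sequences are truncated to their last \code{window_bp} bases (the bases
#'   adjacent to the transcription start site), shorter ones scanned in full.
#' @param strands \code{"both"} (default) or \code{"forward_only"} to mimic
#'   a literal text-pattern search.
#' @return A \code{ScanConfig} list.
#' @export
scan_config <- function(pattern = "AGGTCANNNNAGGTCA", max_mismatch = 4,
                        window_bp = 5000, strands = c("both", "forward_only")) {
  strands <- match.arg(strands)
  pattern <- toupper(pattern)
  if (!grepl("^[ACGTN]+$", pattern)) stop("pattern must be over A,C,G,T,N")
  n_info <- sum(strsplit(pattern, "")[[1]] != "N")
  if (max_mismatch < 0 || max_mismatch > n_info)
    stop("max_mismatch must be in 0..", n_info)
  if (window_bp < 1) stop("window_bp must be positive")
  structure(list(pattern = pattern, max_mismatch = as.integer(max_mismatch),
                 window_bp = as.integer(window_bp), strands = strands),
            class = "ScanConfig")
}

# reverse complement of a character string (N self-complementary)
revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Hamming mismatch profile of a pattern against every window of seq_chars:
# for each informative (non-N) pattern position, compare the shifted
# character vector; an N in the sequence never equals a concrete base and so
# counts as a mismatch there.
mismatch_profile <- function(seq_chars, pat_chars) {
  k <- length(pat_chars)
  n_win <- length(seq_chars) - k + 1
  if (n_win < 1) return(integer(0))
  mm <- integer(n_win)
  starts <- seq_len(n_win)
  for (o in which(pat_chars != "N"))
    mm <- mm + (seq_chars[starts + o - 1L] != pat_chars[o])
  mm
}

#' Scan one promoter for a degenerate element under a mismatch budget
#'
#' Slides the pattern over every start position (overlaps allowed) on the
#' requested strands, counting mismatches only at non-N pattern positions.
#' Reverse-strand hits report the reverse-complement window as read 5'->3'
#' on the minus strand, with \code{start} still the 0-based leftmost base of
#' the window on the forward coordinate system.
#'
#' @param seq nucleotide string over \{A,C,G,T,N\} (case-insensitive).
#' @param config a \code{\link{scan_config}}.
#' @return Data frame of hits sorted by start then strand (+ before -):
#'   \code{start} (0-based), \code{strand}, \code{matched_seq},
#'   \code{mismatches}. A sequence shorter than the pattern yields zero rows.
#' @examples
#' scan_promoter("AGGTCATTTTAGGTCA", scan_config(max_mismatch = 0))
#' @export
scan_promoter <- function(seq, config = scan_config()) {
  stopifnot(inherits(config, "ScanConfig"))
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]*$", seq)) stop("sequence must be over A,C,G,T,N")
  if (nchar(seq) > config$window_bp)
    seq <- substr(seq, nchar(seq) - config$window_bp + 1L, nchar(seq))
  k <- nchar(config$pattern)
  L <- nchar(seq)
  empty <- data.frame(start = integer(0), strand = character(0),
                      matched_seq = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (L < k) return(empty)
  pat_chars <- strsplit(config$pattern, "")[[1]]
  seq_chars <- strsplit(seq, "")[[1]]

  collect <- function(chars, full, strand) {
    mm <- mismatch_profile(chars, pat_chars)
    hit <- which(mm <= config$max_mismatch)
    if (!length(hit)) return(empty)
    st <- hit - 1L  # 0-based on the scanned strand
    data.frame(
      start = if (strand == "+") st else L - k - st,
      strand = strand,
      matched_seq = substring(full, hit, hit + k - 1L),
      mismatches = mm[hit],
      stringsAsFactors = FALSE)
  }
  hits <- collect(seq_chars, seq, "+")
  if (config$strands == "both") {
    rc <- revcomp_str(seq)
    hits <- rbind(hits, collect(strsplit(rc, "")[[1]], rc, "-"))
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a set of promoters
#'
#' Applies \code{\link{scan_promoter}} to every record and returns a
#' BED-like table (0-based, half-open coordinates). In
#' \code{"best_per_gene"} mode only the single best hit per gene is kept:
#' fewest mismatches, then smallest start, then + strand.
#'
#' @param promoters named \code{DNAStringSet} or named character vector of
#'   promoter sequences (names are gene ids; duplicates are an error).
#' @param config a \code{\link{scan_config}}.
#' @param mode \code{"all_hits"} or \code{"best_per_gene"}.
#' @return Data frame: \code{gene_id}, \code{start}, \code{end},
#'   \code{matched_seq}, \code{mismatches}, \code{strand}.
#' @export
scan_set <- function(promoters, config = scan_config(),
                     mode = c("all_hits", "best_per_gene")) {
  mode <- match.arg(mode)
  seqs <- stats::setNames(as.character(promoters), names(promoters))
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("promoters must be named by gene id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate gene ids in promoter set")
  per_gene <- lapply(names(seqs), function(g) {
    h <- scan_promoter(seqs[[g]], config)
    if (nrow(h) == 0) return(NULL)
    if (mode == "best_per_gene") {
      h <- h[order(h$mismatches, h$start, h$strand), , drop = FALSE][1, ]
    }
    cbind(gene_id = g, h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), start = integer(0),
                      strand = character(0), matched_seq = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  k <- nchar(config$pattern)
  out <- data.frame(gene_id = out$gene_id, start = out$start,
                    end = out$start + k, matched_seq = out$matched_seq,
                    mismatches = out$mismatches, strand = out$strand,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Write scanner hits as a BED6-like TSV
#'
#' Columns: gene_id (chrom surrogate), start, end, name (matched sequence),
#' score (mismatch count), strand. Coordinates 0-based, half-open.
#'
#' @param hits output of \code{\link{scan_set}}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_hits_bed <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Build a position-frequency motif model from hit sequences
#'
#' Stacks equal-length hit sequences into per-position base counts,
#' frequencies, information content and a called consensus. Information
#' content at a position is \code{2 + sum_b f_b log2 f_b} bits (0 log 0 = 0):
#' 2 bits for an invariant position, 0 for a uniform one. The consensus
#' letter is the most frequent base, uppercase if its frequency is at least
#' \code{upper}, lowercase if at least \code{lower}, else \code{'n'}
#' (ties broken in A,C,G,T order).
#'
#' @param hit_sequences character vector of equal-length sequences over
#'   \{A,C,G,T\}.
#' @param upper,lower consensus case thresholds (defaults 0.75 and 0.5).
#' @return A \code{MotifModel}: list with \code{counts} (positions x 4),
#'   \code{freq}, \code{ic} (bits per position), \code{consensus},
#'   \code{n_sequences}.
#' @examples
#' m <- build_motif(rep("AGGTCATTTTAGGTCA", 23))
#' m$consensus
#' @export
build_motif <- function(hit_sequences, upper = 0.75, lower = 0.5) {
  if (length(hit_sequences) == 0) stop("at least one hit sequence required")
  hit_sequences <- toupper(hit_sequences)
  k <- unique(nchar(hit_sequences))
  if (length(k) != 1) stop("hit sequences must all have the same length")
  if (!all(grepl("^[ACGT]+$", hit_sequences)))
    stop("hit sequences must be over A,C,G,T only")
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(hit_sequences, ""))
  counts <- t(apply(mat, 2, function(col)
    table(factor(col, levels = bases))))
  counts <- matrix(as.integer(counts), ncol = 4,
                   dimnames = list(position = seq_len(k), base = bases))
  freq <- counts / length(hit_sequences)
  ic <- apply(freq, 1, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  cons <- vapply(seq_len(k), function(i) {
    f <- freq[i, ]
    b <- bases[which.max(f)]
    if (max(f) >= upper) b
    else if (max(f) >= lower) tolower(b)
    else "n"
  }, "")
  structure(list(counts = counts, freq = freq, ic = ic,
                 consensus = paste(cons, collapse = ""),
                 n_sequences = length(hit_sequences)),
            class = "MotifModel")
}

#' @export
print.MotifModel <- function(x, ...) {
  cat("MotifModel over", x$n_sequences, "sequences\n")
  cat("consensus:", x$consensus, "\n")
  cat("IC (bits):", paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' Write a motif count matrix as TSV
#'
#' Position by A,C,G,T counts, consumable by logo renderers.
#'
#' @param motif a \code{MotifModel}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_motif_matrix <- function(motif, path) {
  df <- data.frame(position = seq_len(nrow(motif$counts)), motif$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
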