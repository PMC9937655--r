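# Independent brute-force oracles used across tests. These deliberately use
# the most naive possible algorithms so they share no code path with the
# package implementation.

# enumerate every window x strand and count Hamming mismatches at non-N
# pattern positions; returns hits sorted like scan_promoter
oracle_scan <- function(seq, pattern = "AGGTCANNNNAGGTCA", budget = 4,
                        strands = "both") {
  seq <- toupper(seq)
  k <- nchar(pattern)
  pat <- strsplit(pattern, "")[[1]]
  info <- which(pat != "N")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  rows <- list()
  scan1 <- function(s, strand) {
    L <- nchar(s)
    if (L < k) return()
    for (st in 0:(L - k)) {
      win <- substr(s, st + 1, st + k)
      wc <- strsplit(win, "")[[1]]
      mm <- sum(wc[info] != pat[info])
      if (mm <= budget) {
        fwd_start <- if (strand == "+") st else L - k - st
        rows[[length(rows) + 1]] <<- data.frame(
          start = fwd_start, strand = strand, matched_seq = win,
          mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  scan1(seq, "+")
  if (strands == "both") scan1(rc(seq), "-")
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(start = integer(0), strand = character(0),
                      matched_seq = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# N50/N90 by explicit descending walk
oracle_nX <- function(lengths, frac) {
  srt <- sort(lengths, decreasing = TRUE)
  tot <- sum(as.numeric(srt))
  acc <- 0
  for (l in srt) {
    acc <- acc + l
    if (acc >= frac * tot) return(l)
  }
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}
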