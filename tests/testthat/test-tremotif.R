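test_that("exact matches are found on both strands with 0-based starts", {
  cfg0 <- scan_config(max_mismatch = 0)
  h <- scan_promoter("AGGTCATTTTAGGTCA", cfg0)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 0)
  expect_equal(h$mismatches, 0)
  expect_equal(h$strand, "+")
  # reverse complement of the same element, scanned on both strands
  h2 <- scan_promoter("TGACCTAAAATGACCT", cfg0)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 0)
  expect_equal(h2$matched_seq, "AGGTCATTTTAGGTCA")
  # too-short sequence: empty result, not an error
  expect_equal(nrow(scan_promoter("AGGTCA", cfg0)), 0)
  expect_error(scan_promoter("AGGXCATTTTAGGTCA", cfg0), "A,C,G,T,N")
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(21)
  for (i in 1:100) {
    s <- random_dna(1000)
    for (budget in 0:4) {
      for (str in c("both", "forward_only")) {
        got <- scan_promoter(s, scan_config(max_mismatch = budget,
                                            strands = str))
        want <- oracle_scan(s, budget = budget,
                            strands = if (str == "both") "both" else "+")
        expect_identical(got, want)
      }
    }
  }
})

test_that("sequence N counts as a mismatch at half-site positions only", {
  # N at pattern position 1 (half-site): one mismatch
  h <- scan_promoter("NGGTCATTTTAGGTCA", scan_config(max_mismatch = 1,
                                                     strands = "forward_only"))
  expect_equal(h$mismatches, 1)
  # N in the spacer: free
  h2 <- scan_promoter("AGGTCANNNNAGGTCA", scan_config(max_mismatch = 0,
                                                      strands = "forward_only"))
  expect_equal(h2$mismatches, 0)
})

test_that("strand involution maps coordinates start -> len-16-start", {
  set.seed(22)
  s <- random_dna(300)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  cfg <- scan_config(max_mismatch = 3)
  a <- scan_promoter(s, cfg)
  b <- scan_promoter(rc, cfg)
  flip <- data.frame(start = nchar(s) - 16 - b$start,
                     strand = ifelse(b$strand == "+", "-", "+"),
                     matched_seq = b$matched_seq, mismatches = b$mismatches,
                     stringsAsFactors = FALSE)
  key <- function(d) sort(paste(d$start, d$strand, d$matched_seq, d$mismatches))
  expect_identical(key(a), key(flip))
})

test_that("scan_set keeps the best hit per gene with fixed tie-breaks", {
  proms <- c(
    g_two  = paste0("AGGTCAACGTAGGTCA", strrep("C", 20), "AGGTCATTTTAGGTCA"),
    g_none = strrep("C", 60))
  h <- scan_set(proms, scan_config(max_mismatch = 0), mode = "best_per_gene")
  expect_equal(nrow(h), 1)
  expect_equal(h$gene_id, "g_two")
  expect_equal(h$start, 0)  # tie on mismatches -> leftmost
  expect_equal(h$end, 16)
  # budget monotonicity: higher budget is a superset
  set.seed(23)
  s <- random_dna(800)
  h2 <- scan_set(c(g = s), scan_config(max_mismatch = 2), mode = "all_hits")
  h4 <- scan_set(c(g = s), scan_config(max_mismatch = 4), mode = "all_hits")
  expect_true(all(paste(h2$start, h2$strand) %in% paste(h4$start, h4$strand)))
  # duplicate ids rejected; empty set allowed
  expect_error(scan_set(c(a = s, a = s), scan_config()), "duplicate")
  e <- scan_set(setNames(character(0), character(0)), scan_config())
  expect_equal(nrow(e), 0)
})

test_that("motif counts, information content and consensus follow the rules", {
  m <- build_motif(rep("AGGTCATTTTAGGTCA", 23))
  expect_true(all(abs(m$ic - 2) < 1e-12))
  expect_identical(m$consensus, "AGGTCATTTTAGGTCA")
  expect_true(all(rowSums(m$counts) == 23))
  # uniform column: 0 bits, 'n'; half/half column: exactly 1 bit, lowercase
  seqs <- c("AGGTCAATTTAGGTCA", "AGGTCACTTTAGGTCA",
            "AGGTCAGTTTAGGTCA", "AGGTCATTTTAGGTCA")
  m2 <- build_motif(seqs)
  expect_equal(unname(m2$ic[7]), 0)
  expect_identical(substr(m2$consensus, 7, 7), "n")
  seqs3 <- c("AGGTCAATTTAGGTCA", "AGGTCAATTTAGGTCA",
             "AGGTCACTTTAGGTCA", "AGGTCACTTTAGGTCA")
  m3 <- build_motif(seqs3)
  expect_equal(unname(m3$ic[7]), 1)          # 2 + 2*(0.5*log2 0.5) = 1
  expect_identical(substr(m3$consensus, 7, 7), "a")  # tie -> first in A,C,G,T
  expect_error(build_motif(character(0)), "at least one")
  expect_error(build_motif(c("ACGT", "ACGTA")), "same length")
  expect_error(build_motif("AGGTCANNNNAGGTCA"), "A,C,G,T")
})

test_that("frequency columns sum to one and IC stays within [0,2]", {
  set.seed(24)
  seqs <- vapply(1:50, function(i) random_dna(16), "")
  m <- build_motif(seqs)
  expect_equal(unname(rowSums(m$freq)), rep(1, 16))
  expect_true(all(m$ic >= 0 & m$ic <= 2))
  expect_equal(nchar(m$consensus), 16)
})
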